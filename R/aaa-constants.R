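#' Pool names, in canonical order
#'
#' The twelve dynamic carbon pools: nine biotic guilds followed by litter,
#' SOM and DOM. All pool values are in g C m^-3 of soil.
#' @export
POOLS <- c("bacteria", "fungi", "mycorrhiza", "bacterivores", "fungivores",
           "detritivores", "engineers", "herbivores", "predators",
           "litter", "SOM", "DOM")

#' Guild names (the nine biotic pools)
#' @export
GUILDS <- POOLS[1:9]

#' Pore-size class names, smallest to largest
#'
#' Diameter ranges: inaccessible < 0.1 um, bacterial 0.1-2 um,
#' micro 2-30 um, meso 30 um-1.5 mm, macro > 1.5 mm.
#' @export
PORE_CLASSES <- c("inaccessible", "bacterial", "micro", "meso", "macro")
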