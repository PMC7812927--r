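# Site configuration files: a flat YAML dialect mapping directly onto the
# site_config() arguments.

#' Read a site configuration from YAML
#'
#' The file may contain any subset of the [site_config()] argument lists
#' (`pools0`, `texture`, `quality`, `inputs`, `pores`, `hydro`, `dom`,
#' `bioturb`, `modifiers`) as flat key-value maps; missing entries fall
#' back to the packaged defaults. Unknown top-level keys are an error in
#' strict mode, a warning otherwise.
#'
#' @param path YAML file path.
#' @param strict error (rather than warn) on unknown keys.
#' @return an `sfw_config`.
#' @export
read_site_config <- function(path, strict = TRUE) {
  cfg <- yaml::read_yaml(path)
  known <- c("pools0", "texture", "quality", "inputs", "pores", "hydro",
             "dom", "bioturb", "modifiers")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    msg <- paste("unknown configuration keys:",
                 paste(unknown, collapse = ", "))
    if (strict) stop(msg) else warning(msg)
    cfg <- cfg[intersect(names(cfg), known)]
  }
  if (!is.null(cfg$pools0)) cfg$pools0 <- unlist(cfg$pools0)
  if (!is.null(cfg$pores$frac)) cfg$pores$frac <- unlist(cfg$pores$frac)
  do.call(site_config, cfg)
}

#' Write a site configuration to YAML
#'
#' Writes the configurable parts of an `sfw_config` (not the derived
#' quantities or the guild/diet tables, which travel as CSV).
#'
#' @param config an `sfw_config`.
#' @param path output path.
#' @export
write_site_config <- function(config, path) {
  stopifnot(inherits(config, "sfw_config"))
  out <- list(pools0 = as.list(config$pools0), texture = config$texture,
              quality = config$quality, inputs = config$inputs,
              pores = modifyList(config$pores,
                                 list(frac = as.list(config$pores$frac))),
              hydro = config$hydro, dom = config$dom,
              bioturb = config$bioturb, modifiers = config$modifiers)
  yaml::write_yaml(out, path)
}
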