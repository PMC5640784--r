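# Plain-text I/O: YAML run configuration and parameter files, tab-separated
# measurement tables. No binary formats.

#' Read a run configuration
#'
#' YAML file with optional fields: seed, mode ("mouse"/"human"), out_dir,
#' cap, max_doses, perturbation, il6, horizon, tolerance overrides (rtol,
#' atol) and parameter overrides (named list `parameters`). Missing fields
#' take the defaults below.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @return named list of settings.
#' @export
read_config <- function(path = NULL) {
  defaults <- list(seed = 1, mode = "mouse", out_dir = "results",
                   cap = 500, max_doses = 3, perturbation = 0.5,
                   il6 = 100, horizon = 24, rtol = 1e-8, atol = 1e-12,
                   parameters = list())
  if (is.null(path)) return(defaults)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  bad <- setdiff(names(cfg), names(defaults))
  if (length(bad)) {
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  utils::modifyList(defaults, cfg)
}

#' Write a named parameter vector to YAML
#' @param params named numeric vector.
#' @param path output path.
#' @export
write_params <- function(params, path) {
  yaml::write_yaml(as.list(params), path)
  invisible(path)
}

#' Read a named parameter vector from YAML
#' @param path YAML file path.
#' @return named numeric vector.
#' @export
read_params <- function(path) {
  x <- yaml::read_yaml(path)
  v <- unlist(x)
  if (!is.numeric(v)) stop("non-numeric parameter value in ", path,
                           call. = FALSE)
  v
}

#' Write a measurement or result table as tab-separated text
#' @param x data.frame.
#' @param path output path.
#' @export
write_dataset <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table written by [write_dataset()]
#' @param path file path.
#' @return data.frame.
#' @export
read_dataset <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
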