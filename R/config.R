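# Plain-text run configuration: INI-like sections [model], [numerics],
# [initial], [run] with `key = value` lines; `#` starts a comment. Keys are
# named exactly as the model_params() fields.

config_keys <- list(
  model = c("p", "q", "q_v", "alpha", "beta", "D_U", "D_P", "D_v", "K",
            "movement", "dimension"),
  numerics = c("tau", "delta", "dx", "dt", "L"),
  initial = c("R_u", "R_v", "R_i", "V_0", "u_height"),
  run = c("horizon", "seed", "replicates", "record_every", "model",
          "alpha_values", "q_v_values", "D_v_values", "level")
)

#' Read a run configuration file
#'
#' @param path Path to the config file.
#' @return A nested named list, one entry per section.
#' @seealso [params_from_config()]; bundled examples under
#'   `system.file("extdata", package = "oncowave")`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  cfg <- list()
  section <- NULL
  for (ln in seq_along(lines)) {
    line <- sub("#.*$", "", lines[ln])
    line <- trimws(line)
    if (line == "") next
    if (grepl("^\\[.+\\]$", line)) {
      section <- sub("^\\[(.+)\\]$", "\\1", line)
      if (!section %in% names(config_keys)) {
        stop(sprintf("line %d: unknown section [%s]", ln, section),
             call. = FALSE)
      }
      cfg[[section]] <- cfg[[section]] %||% list()
      next
    }
    if (is.null(section)) {
      stop(sprintf("line %d: key outside any [section]", ln), call. = FALSE)
    }
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) {
      stop(sprintf("line %d: expected `key = value`", ln), call. = FALSE)
    }
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    if (!key %in% config_keys[[section]]) {
      stop(sprintf("line %d: unknown key `%s` in section [%s]",
                   ln, key, section), call. = FALSE)
    }
    num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
    cfg[[section]][[key]] <- if (anyNA(num)) val else num
  }
  cfg
}

#' Build model parameters from a configuration
#'
#' @param cfg A list from [read_config()].
#' @return An [model_params()] object (config values override defaults).
#' @export
params_from_config <- function(cfg) {
  args <- c(cfg$model,
            cfg$numerics[intersect(names(cfg$numerics), c("tau", "delta"))],
            cfg$initial[intersect(names(cfg$initial),
                                  c("R_u", "R_v", "R_i", "V_0"))])
  do.call(model_params, args)
}
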