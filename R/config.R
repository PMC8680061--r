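#' Default run configuration
#'
#' The configuration keys understood by the package, with their defaults:
#' encoder kind and maximum packed lengths (250 for the MRC packing, which
#' must also hold the query; 230 for the one-pass packing), the MRC query
#' strategy, the one-pass definition source and dimension, and the
#' optimisation settings.
#'
#' @return Nested named list of defaults.
#' @export
default_config <- function() {
  list(
    encoder = list(kind = "tiny", name_or_path = NULL,
                   d = 32L, n_layers = 2L,
                   max_len_mrc = 250L, max_len_sone = 230L),
    mrc = list(query_strategy = "guideline"),
    sone = list(definition_source = "guideline", d_e = 300L),
    train = list(steps = 300L, batch_size = 20L, lr = 5e-3, seed = 1L)
  )
}

#' Read a YAML run configuration
#'
#' Reads a YAML file and merges it over \code{\link{default_config}}
#' (recursively; keys in the file win).
#'
#' @param path YAML file path.
#' @return Nested named list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]])) {
      merge_config(base[[k]], user[[k]])
    } else {
      user[[k]]
    }
  }
  base
}

#' Fit a model from a run configuration
#'
#' Thin wrapper translating a configuration list (see
#' \code{\link{read_run_config}}) into a \code{\link{definition_ner}} call.
#' Only the bundled trainable encoder is runnable here; a configuration
#' asking for \code{encoder.kind = "pretrained"} is rejected with a clear
#' error since no pretrained weights ship with the package.
#'
#' @param corpus Corpus as in \code{\link{definition_ner}}.
#' @param config Configuration list.
#' @param method \code{"mrc"} or \code{"sone"}.
#' @param ... Overrides forwarded to \code{\link{definition_ner}}.
#' @return A fitted \code{definition_ner}.
#' @export
fit_from_config <- function(corpus, config, method = c("mrc", "sone"), ...) {
  method <- match.arg(method)
  if (!identical(config$encoder$kind, "tiny")) {
    defner_error("only encoder.kind = 'tiny' is runnable; pretrained weights are not bundled",
                 "defner_config_error")
  }
  definition_ner(
    corpus, method = method,
    query_strategy = config$mrc$query_strategy,
    definition_source = config$sone$definition_source,
    d = config$encoder$d, n_layers = config$encoder$n_layers,
    d_e = config$sone$d_e,
    max_len = if (method == "mrc") config$encoder$max_len_mrc
              else config$encoder$max_len_sone,
    steps = config$train$steps, batch_size = config$train$batch_size,
    lr = config$train$lr, seed = config$train$seed, ...
  )
}
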