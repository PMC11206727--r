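#' Read and write a population model as a YAML config
#'
#' The config mirrors the parameter tables field-for-field: typical values,
#' BSV as log-scale SDs (omega), optional random-effect correlations,
#' covariate effects, the residual-error model and fixed flags.
#'
#' @param model a [population_model()]
#' @param path file path (conventionally `.yaml`)
#' @return `read_model_config` returns a [population_model()]
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_model_config(model_etanercept(), f)
#' read_model_config(f)
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "population_model"))
  th <- model$typical
  cfg <- list(
    name = model$name,
    typical = Filter(Negate(is.null),
                     list(CL = th$CL, VD = th$VD, ka = th$ka,
                          Q = th$Q, VP = th$VP)),
    bsv_omega = as.list(model$bsv),
    bsv_corr = if (!is.null(model$bsv_corr)) {
      list(parameters = colnames(model$bsv_corr),
           values = apply(model$bsv_corr, 1, as.list, simplify = FALSE))
    },
    covariate_effects = lapply(model$covariate_effects, function(ef)
      Filter(Negate(is.null),
             list(parameter = ef$parameter, covariate = ef$covariate,
                  form = ef$form, coefficient = ef$coefficient,
                  reference = ef$reference))),
    error = list(kind = model$error_model$kind,
                 sigma_add = model$error_model$sigma_add,
                 sigma_prop = model$error_model$sigma_prop),
    fixed = as.list(model$fixed))
  yaml::write_yaml(Filter(Negate(is.null), cfg), path, precision = 15)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$typical) || is.null(cfg$error))
    stop_input("config must contain 'typical' and 'error' sections")
  tv <- cfg$typical
  bsv <- unlist(cfg$bsv_omega) %||% numeric(0)
  corr <- NULL
  if (!is.null(cfg$bsv_corr)) {
    nm <- unlist(cfg$bsv_corr$parameters)
    corr <- do.call(rbind, lapply(cfg$bsv_corr$values, unlist))
    dimnames(corr) <- list(nm, nm)
  }
  effects <- lapply(cfg$covariate_effects %||% list(), function(ef)
    covariate_effect(ef$parameter, ef$covariate, ef$coefficient,
                     reference = ef$reference))
  population_model(
    typical = pk_params(CL = tv$CL, VD = tv$VD, ka = tv$ka,
                        Q = tv$Q, VP = tv$VP),
    bsv = if (length(bsv)) bsv else numeric(0),
    bsv_corr = corr, covariate_effects = effects,
    error_model = residual_error(cfg$error$kind,
                                 sigma_add = cfg$error$sigma_add %||% 0,
                                 sigma_prop = cfg$error$sigma_prop %||% 0),
    fixed = unlist(cfg$fixed) %||% character(0),
    name = cfg$name)
}
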