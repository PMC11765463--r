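# Plain-text (YAML) serialisation of generative-model components, with
# explicit shape metadata so files are self-describing. Loaders re-validate
# on read.

tensor_to_list <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  list(dim = as.integer(d), values = as.numeric(x))
}

tensor_from_list <- function(x) {
  d <- as.integer(unlist(x$dim))
  vals <- as.numeric(unlist(x$values))
  if (length(vals) != prod(d))
    stop("tensor value count does not match declared dimensions")
  if (length(d) == 1L) vals else array(vals, dim = d)
}

#' Write model components to a YAML file
#'
#' Serialises shape metadata and the A/B/C/D/E components to a structured
#' plain-text file that [read_model_yaml()] can restore losslessly.
#'
#' @param model List with elements `A`, `B`, `C`, `D`, `E` (C/D/E optional).
#' @param shape The [model_shape()] the components conform to.
#' @param path Output file path.
#' @export
write_model_yaml <- function(model, shape, path) {
  doc <- list(
    shape = list(num_obs = as.integer(shape$num_obs),
                 num_states = as.integer(shape$num_states),
                 num_controls = as.integer(shape$num_controls),
                 policy_length = as.integer(shape$policy_length)),
    A = lapply(model$A, tensor_to_list),
    B = lapply(model$B, tensor_to_list))
  if (!is.null(model$C)) doc$C <- lapply(model$C, as.numeric)
  if (!is.null(model$D)) doc$D <- lapply(model$D, as.numeric)
  if (!is.null(model$E)) doc$E <- as.numeric(model$E)
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' Read model components from a YAML file
#'
#' @param path File written by [write_model_yaml()].
#' @return A list with elements `shape`, `A`, `B`, `C`, `D`, `E`.
#' @export
read_model_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$shape)) stop("model file lacks shape metadata")
  shape <- model_shape(num_obs = unlist(doc$shape$num_obs),
                       num_states = unlist(doc$shape$num_states),
                       num_controls = unlist(doc$shape$num_controls),
                       policy_length = doc$shape$policy_length)
  model <- list(
    A = lapply(doc$A, tensor_from_list),
    B = lapply(doc$B, tensor_from_list),
    C = if (!is.null(doc$C)) lapply(doc$C, function(x) as.numeric(unlist(x))),
    D = if (!is.null(doc$D)) lapply(doc$D, function(x) as.numeric(unlist(x))),
    E = if (!is.null(doc$E)) as.numeric(unlist(doc$E)))
  viol <- validate_model(model$A, model$B, model$C, model$D, model$E, shape)
  if (length(viol) > 0)
    stop("invalid model file:\n  ", paste(viol, collapse = "\n  "))
  c(list(shape = shape), model)
}
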