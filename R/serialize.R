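# Model checkpoints: a single JSON container holding a manifest (class,
# layer sizes, seeds) and full-precision parameters. JSON keeps the
# checkpoints diffable and free of binary-format dependencies; models at
# study scale are a few tens of MB, acceptable for an offline pipeline.

mlp_to_list <- function(net) {
  # parameters stored as %.17g strings: exact double round trip, which
  # plain JSON numbers do not guarantee
  list(sizes = net$sizes, out = net$out,
       W = lapply(net$W, function(w) list(dim = dim(w),
                                          x = sprintf("%.17g", as.numeric(w)))),
       b = lapply(net$b, function(b) sprintf("%.17g", b)))
}

mlp_from_list <- function(l) {
  net <- list(
    W = lapply(l$W, function(w) {
      d <- as.integer(unlist(w$dim))
      matrix(as.numeric(unlist(w$x)), d[1], d[2])
    }),
    b = lapply(l$b, function(b) as.numeric(unlist(b))),
    sizes = as.integer(unlist(l$sizes)), out = l$out)
  class(net) <- "mlp"
  net
}

#' Save / load a model checkpoint
#'
#' Supports `multibranch_model` and `feature_generator` objects. The file is
#' a JSON container with a manifest and the parameters at full precision.
#'
#' @param model the model object.
#' @param path output file path (conventionally `.json`).
#' @return invisibly `path`; `load_model()` returns the model.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "multibranch_model")) {
    obj <- list(manifest = list(class = "multibranch_model", K = model$K,
                                block_dims = model$block_dims,
                                n_blocks = n_mlp_blocks(model)),
                branches = lapply(model$branches, mlp_to_list),
                fusion = mlp_to_list(model$fusion))
  } else if (inherits(model, "feature_generator")) {
    obj <- list(manifest = list(class = "feature_generator",
                                noise_dim = model$noise_dim),
                net = mlp_to_list(model))
  } else stop("unsupported model class")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  cls <- obj$manifest$class
  if (cls == "multibranch_model") {
    m <- structure(list(branches = lapply(obj$branches, mlp_from_list),
                        fusion = mlp_from_list(obj$fusion),
                        block_dims = as.integer(unlist(obj$manifest$block_dims)),
                        K = as.integer(obj$manifest$K)),
                   class = "multibranch_model")
    return(m)
  }
  if (cls == "feature_generator") {
    net <- mlp_from_list(obj$net)
    net$noise_dim <- as.integer(obj$manifest$noise_dim)
    class(net) <- c("feature_generator", "mlp")
    return(net)
  }
  stop("unknown checkpoint class: ", cls)
}

#' Write / read subject metadata as CSV
#'
#' @param records a [subject_records()] data.frame.
#' @param path CSV path.
#' @return invisibly `path` (write) or a `subject_records` (read).
#' @export
write_subject_records <- function(records, path) {
  data.table::fwrite(as.data.frame(records), path)
  invisible(path)
}

#' @rdname write_subject_records
#' @export
read_subject_records <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  subject_records(df$subject_id, df$visit_id, df$diagnosis, df$age, df$sex,
                  df$icv, df$field_strength, df$site, df$scanner)
}
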