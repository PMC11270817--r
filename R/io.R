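# Plain-text interchange: sample sets as CSV with a JSON sidecar,
# system definitions as JSON, traces as CSV.

#' Write a sample batch to CSV (+ JSON sidecar)
#'
#' One configuration per row, columns `x1..xD`; a sidecar
#' `<path>.json` records origin, state label, seed and any sampler
#' settings.
#'
#' @param batch a `sample_batch`.
#' @param path CSV file path.
#' @param settings optional named list of sampler settings for the
#'   sidecar.
#' @export
write_samples <- function(batch, path, settings = NULL) {
  stopifnot(inherits(batch, "sample_batch"))
  X <- batch$coords
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  utils::write.csv(as.data.frame(X), path, row.names = FALSE)
  meta <- list(format = "flowfe-samples", version = 1L,
               origin = batch$origin, state = batch$state,
               n = nrow(X), D = ncol(X),
               seed = attr(batch, "seed"),
               settings = settings)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a sample batch written by [write_samples()]
#' @param path CSV file path.
#' @return a `sample_batch`.
#' @export
read_samples <- function(path) {
  X <- as.matrix(utils::read.csv(path))
  side <- paste0(path, ".json")
  origin <- "md"; state <- NA_integer_
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    origin <- meta$origin
    state <- if (is.null(meta$state)) NA_integer_ else meta$state
  }
  sample_batch(X, origin = origin, state = state)
}

#' Write a toy-system definition to JSON
#' @param sys a `toy_system`.
#' @param path file path.
#' @export
write_system <- function(sys, path) {
  stopifnot(inherits(sys, "toy_system"))
  obj <- list(format = "flowfe-system", version = 1L, type = "toy",
              centers = apply(sys$centers, 1L, identity, simplify = FALSE),
              stiffness = sys$stiffness, depth = sys$depth,
              group = sys$group, a = sys$a, b = sys$b)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a toy-system definition written by [write_system()]
#' @param path file path.
#' @return a `toy_system`.
#' @export
read_system <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "flowfe-system")) stop("not a system file")
  centers <- do.call(rbind, lapply(obj$centers, function(v) as.numeric(unlist(v))))
  for (nm in c("stiffness", "depth", "group", "a", "b")) {
    obj[[nm]] <- as.numeric(unlist(obj[[nm]]))
  }
  build_toy_system(centers, obj$stiffness, obj$depth, obj$group,
                   a = obj$a, b = obj$b)
}

#' Write a convergence trace to CSV
#' @param trace trace data frame.
#' @param path file path.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' Read a convergence trace from CSV
#' @param path file path.
#' @export
read_trace <- function(path) {
  utils::read.csv(path, colClasses = c(target = "character",
                                       split = "character"))
}
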