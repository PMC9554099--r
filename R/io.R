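# Serialization: networks as JSON (full-precision doubles, bit-exact round
# trips), spike rasters as headered TSV.

#' Save a network to JSON
#'
#' Writes weights, biases, feedback matrix, parameters, configuration,
#' backend, seed, and (optionally) the current global RNG state with full
#' double precision, so that `load_state()` restores the network bit-exactly
#' and resumed training matches uninterrupted training.
#'
#' @param net an [build_network()] network.
#' @param path output file path.
#' @param include_rng store the current `.Random.seed` alongside the
#'   network.
#' @return `path`, invisibly.
#' @export
save_state <- function(net, path, include_rng = TRUE) {
  stopifnot(inherits(net, "snn_network"))
  obj <- list(
    format = "mlifsnn-network", version = 1L,
    sizes = c(net$n_in, net$n_hidden, net$n_out),
    W0 = net$W0, b0 = net$b0, W1 = net$W1, b1 = net$b1, Y = net$Y,
    params = unclass(net$params), config = unclass(net$config),
    backend = net$backend, seed = net$seed)
  if (include_rng) {
    obj$rng_state <- get0(".Random.seed", globalenv())
  }
  # I(17) = 17 significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a network saved by [save_state()]
#'
#' @param net_path path written by [save_state()].
#' @param restore_rng if a RNG state was stored, restore it into the
#'   global environment.
#' @return the restored `snn_network`.
#' @export
load_state <- function(net_path, restore_rng = TRUE) {
  obj <- tryCatch(jsonlite::read_json(net_path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("load_state: cannot parse '", net_path, "': ",
                         conditionMessage(e))
                  })
  if (!identical(obj$format, "mlifsnn-network")) {
    stop("load_state: '", net_path, "' is not a saved network")
  }
  sizes <- as.integer(obj$sizes)
  if (length(sizes) != 3 ||
      !all(dim(obj$W0) == c(sizes[2], sizes[1])) ||
      !all(dim(obj$W1) == c(sizes[3], sizes[2])) ||
      !all(dim(obj$Y) == c(sizes[2], sizes[3]))) {
    stop("load_state: layer sizes and matrix shapes disagree")
  }
  params <- do.call(network_params, obj$params)
  config <- learning_config(update_sign = obj$config$update_sign,
                            plateau_window_mode = obj$config$plateau_window_mode)
  net <- build_network(sizes[1], sizes[2], sizes[3], params, config,
                       backend = obj$backend, seed = obj$seed)
  net$W0 <- obj$W0; net$b0 <- as.numeric(obj$b0)
  net$W1 <- obj$W1; net$b1 <- as.numeric(obj$b1)
  net$Y <- obj$Y
  if (restore_rng && !is.null(obj$rng_state)) {
    assign(".Random.seed", as.integer(obj$rng_state), globalenv())
  }
  net
}

#' Write a spike raster as headered TSV
#'
#' Plain-text time-by-channel binary matrix with `#`-prefixed header lines
#' carrying `dt`, the channel count and the duration; round trips are
#' bit-exact.
#'
#' @param raster binary matrix, time x channels.
#' @param path output path.
#' @param dt time step (ms) recorded in the header.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path, dt = 1) {
  stopifnot(is.matrix(raster), all(raster %in% c(0, 1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# mlifsnn-raster v1"),
               sprintf("# dt=%g channels=%d duration=%d",
                       dt, ncol(raster), nrow(raster))), con)
  utils::write.table(raster, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a spike raster written by [write_raster()]
#'
#' @param path input path.
#' @return integer matrix with attributes `dt`.
#' @export
read_raster <- function(path) {
  header <- readLines(path, n = 2)
  if (!startsWith(header[1], "# mlifsnn-raster")) {
    stop("read_raster: '", path, "' is not a raster file")
  }
  kv <- strsplit(sub("^# ", "", header[2]), " ")[[1]]
  meta <- setNames(as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv))
  m <- as.matrix(utils::read.table(path, sep = "\t", comment.char = "#"))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  if (ncol(m) != meta[["channels"]] || nrow(m) != meta[["duration"]]) {
    stop("read_raster: header and body dimensions disagree")
  }
  attr(m, "dt") <- meta[["dt"]]
  m
}
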