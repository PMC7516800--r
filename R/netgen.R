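#' Random normalized connectivity matrices
#'
#' The structural input of the generalized Ising model is a symmetric,
#' non-negative coupling matrix `J` with zero diagonal, interpreted as an
#' undirected weighted graph (for brain applications, e.g. tractography fiber
#' counts between regions). Random networks are fully connected: the
#' `n(n-1)/2` upper-triangle weights are drawn independently from
#' Uniform(0, 1), mirrored, and the whole matrix rescaled so the strongest
#' weight is exactly 1.
#'
#' @param n_nodes Number of nodes (>= 2).
#' @param seed Integer seed; the same `(n_nodes, seed)` pair always yields a
#'   bit-identical matrix.
#' @param label Identifier carried through sweeps and output files.
#' @return A `connectivity` object: the `n x n` weight matrix with attributes
#'   `label` and `seed`.
#' @export
#' @examples
#' J <- generate_random_network(5, seed = 1)
#' max(J)        # exactly 1 after normalization
#' all(diag(J) == 0)
generate_random_network <- function(n_nodes, seed,
                                    label = sprintf("net-s%d", seed)) {
  if (n_nodes < 2) {
    stop("n_nodes must be >= 2: a single node has no couplings", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  W <- matrix(0, n_nodes, n_nodes)
  upper <- upper.tri(W)
  W[upper] <- stats::runif(sum(upper))
  W <- W + t(W)
  J <- normalize_connectivity(W)
  attr(J, "label") <- label
  attr(J, "seed") <- as.integer(seed)
  J
}

#' Normalize a coupling matrix so its strongest weight is 1
#'
#' Divides the matrix by its largest off-diagonal entry and forces the
#' diagonal to zero. Idempotent.
#'
#' @param weights Square, symmetric, non-negative matrix.
#' @return A `connectivity` object (normalized matrix).
#' @export
normalize_connectivity <- function(weights) {
  validate_connectivity(weights, require_normalized = FALSE)
  W <- unclass(as.matrix(weights))
  diag(W) <- 0
  m <- max(W)
  if (m <= 0) {
    stop("degenerate network: all couplings are zero, normalization undefined",
         call. = FALSE)
  }
  W <- W / m
  structure(W, class = c("connectivity", "matrix"))
}

validate_connectivity <- function(weights, require_normalized = FALSE) {
  W <- as.matrix(weights)
  if (nrow(W) != ncol(W)) {
    stop(sprintf("connectivity matrix must be square, got %d x %d",
                 nrow(W), ncol(W)), call. = FALSE)
  }
  if (!isTRUE(all.equal(W, t(W), tolerance = 1e-12, check.attributes = FALSE))) {
    bad <- which(abs(W - t(W)) > 1e-12, arr.ind = TRUE)[1, ]
    stop(sprintf("connectivity matrix must be symmetric; cell (%d, %d) differs from (%d, %d)",
                 bad[1], bad[2], bad[2], bad[1]), call. = FALSE)
  }
  neg <- which(W < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop(sprintf("negative coupling at cell (%d, %d): only ferromagnetic (>= 0) weights are supported",
                 neg[1, 1], neg[1, 2]), call. = FALSE)
  }
  if (require_normalized && max(W - diag(diag(W))) > 1) {
    stop("weights must lie in [0, 1]", call. = FALSE)
  }
  invisible(W)
}

#' Generate an ensemble of random networks
#'
#' Member `k` is generated with a child seed derived deterministically from
#' `(master_seed, k)`, so the whole ensemble is reproducible from one integer
#' and individual members can be regenerated in isolation.
#'
#' @param count Number of networks (>= 1). The study design this emulates used
#'   159 five-node networks.
#' @param n_nodes Nodes per network.
#' @param master_seed Integer seed for the whole ensemble.
#' @return A list of `connectivity` objects with labels `net-001`, ...
#' @export
generate_ensemble <- function(count = 159, n_nodes = 5, master_seed = 1) {
  stopifnot(count >= 1)
  seeds <- derive_seeds(master_seed, count)
  lapply(seq_len(count), function(k) {
    generate_random_network(n_nodes, seed = seeds[k],
                            label = sprintf("net-%03d", k))
  })
}

#' Read / write connectivity matrices as delimited text
#'
#' Matrices are stored as plain whitespace- or comma-separated numeric rows
#' (no header), with an optional JSON sidecar `<path>.json` holding the label
#' and generating seed. Files are validated on read: non-square, asymmetric
#' or negative-weight matrices are rejected with the offending cell named.
#'
#' @param path File path.
#' @return `read_connectivity()` returns a `connectivity` object.
#' @export
read_connectivity <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    as.numeric(strsplit(trimws(l), "[,[:space:]]+")[[1]])
  })
  lens <- vapply(rows, length, integer(1))
  if (length(unique(lens)) != 1 || lens[1] != length(rows)) {
    stop(sprintf("file does not contain a square matrix: %d rows, row lengths %s",
                 length(rows), paste(unique(lens), collapse = "/")), call. = FALSE)
  }
  W <- do.call(rbind, rows)
  validate_connectivity(W)
  meta_path <- paste0(path, ".json")
  label <- NULL; seed <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    label <- meta$label
    seed <- meta$seed
  }
  out <- structure(W, class = c("connectivity", "matrix"))
  attr(out, "label") <- label
  attr(out, "seed") <- seed
  out
}

#' @param J A `connectivity` object or plain matrix.
#' @rdname read_connectivity
#' @export
write_connectivity <- function(J, path) {
  W <- unclass(as.matrix(J))
  utils::write.table(format(W, digits = 17, trim = TRUE, scientific = FALSE),
                     path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  meta <- list(label = attr(J, "label"), seed = attr(J, "seed"),
               n_nodes = nrow(W), normalized = isTRUE(all.equal(max(W), 1)))
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.connectivity <- function(x, ...) {
  cat(sprintf("connectivity matrix: %d nodes%s%s\n", nrow(x),
              if (!is.null(attr(x, "label"))) paste0(", label ", attr(x, "label")) else "",
              if (!is.null(attr(x, "seed"))) paste0(", seed ", attr(x, "seed")) else ""))
  print(unclass(round(x, 4)))
  invisible(x)
}

#' @export
as.matrix.connectivity <- function(x, ...) {
  y <- unclass(x)
  attr(y, "label") <- NULL
  attr(y, "seed") <- NULL
  y
}
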