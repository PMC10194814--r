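#' Read an observation matrix
#'
#' Dense CSV/TSV matrices are read with observations as rows and features as
#' columns (header row = feature names). MatrixMarket (`mtx`) input follows
#' the single-cell convention of features x cells and is transposed to
#' observations x features; a sidecar file of feature names (one per line,
#' first column of a TSV is used) is required and located automatically as
#' `features.tsv` / `genes.tsv` next to the matrix unless given explicitly.
#'
#' @param path input file.
#' @param format `"csv"`, `"tsv"` or `"mtx"` (default guessed from the
#'   extension).
#' @param features path to the MTX feature-name sidecar.
#' @return A `Dataset`: list with `X` (numeric matrix, named columns),
#'   `provenance` (character log of processing steps).
#' @export
read_matrix <- function(path, format = NULL, features = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- format %||% switch(tolower(tools::file_ext(path)),
                               csv = "csv", tsv = "tsv", txt = "tsv",
                               mtx = "mtx",
                               stop("cannot guess format from extension; ",
                                    "pass format="))
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE)
    if (!all(vapply(df, is.numeric, logical(1)))) {
      bad <- names(df)[!vapply(df, is.numeric, logical(1))]
      stop("non-numeric columns: ", paste(bad, collapse = ", "))
    }
    X <- as.matrix(df)
  } else {
    M <- Matrix::readMM(path)
    if (is.null(features)) {
      for (f in c("features.tsv", "genes.tsv")) {
        cand <- file.path(dirname(path), f)
        if (file.exists(cand)) { features <- cand; break }
      }
      if (is.null(features)) stop("MTX input requires a features sidecar ",
                                  "(features.tsv/genes.tsv) or features=")
    }
    fdf <- utils::read.table(features, header = FALSE, sep = "\t")
    if (nrow(fdf) != nrow(M)) stop("features sidecar has ", nrow(fdf),
                                   " rows but matrix has ", nrow(M),
                                   " features")
    X <- t(as.matrix(M))
    colnames(X) <- as.character(fdf[[1]])
  }
  list(X = X, provenance = sprintf("read %s (%s): N=%d, d=%d", path, format,
                                   nrow(X), ncol(X)))
}

#' Write an observation matrix to CSV with full float precision
#'
#' Values are written with 17 significant digits so that a write/read
#' round-trip is bit exact.
#'
#' @param X numeric matrix.
#' @param path output path.
#' @export
write_matrix <- function(X, path) {
  X <- as.matrix(X)
  cn <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  lines <- c(paste(cn, collapse = ","),
             apply(X, 1, function(r)
               paste(formatC(r, digits = 17, format = "g"), collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Preprocess an observation matrix
#'
#' Applies, in order: per-row library-size normalization (each row scaled to
#' the median row total), `log1p`, and per-column standardization
#' (mean-subtraction and unit-variance scaling — the conventional endpoint
#' for expression matrices before Gaussian-family modeling). Each applied
#' step is recorded in the provenance.
#'
#' @param ds a `Dataset` from [read_matrix()] (or a bare matrix).
#' @param libsize,log1p,standardize logical flags, all off by default.
#' @param drop_constant drop zero-variance columns instead of failing when
#'   standardizing.
#' @return The processed `Dataset`.
#' @export
preprocess <- function(ds, libsize = FALSE, log1p = FALSE,
                       standardize = FALSE, drop_constant = FALSE) {
  if (is.matrix(ds)) ds <- list(X = ds, provenance = character(0))
  X <- ds$X
  prov <- ds$provenance
  if (libsize) {
    tot <- rowSums(X)
    if (any(tot <= 0)) stop("library-size normalization requires positive ",
                            "row sums")
    X <- X / tot * stats::median(tot)
    prov <- c(prov, "libsize-normalized rows to the median total")
  }
  if (log1p) {
    X <- base::log1p(X)
    prov <- c(prov, "log1p transform")
  }
  if (standardize) {
    v <- apply(X, 2, stats::var)
    if (any(v == 0)) {
      bad <- colnames(X)[v == 0] %||% which(v == 0)
      if (!drop_constant)
        stop("zero-variance columns under standardize: ",
             paste(bad, collapse = ", "),
             " (use drop_constant = TRUE to drop them)")
      X <- X[, v > 0, drop = FALSE]
      prov <- c(prov, paste("dropped constant columns:",
                            paste(bad, collapse = ", ")))
      v <- v[v > 0]
    }
    X <- scale(X)
    attr(X, "scaled:center") <- NULL
    attr(X, "scaled:scale") <- NULL
    prov <- c(prov, "standardized columns (mean 0, variance 1)")
  }
  list(X = X, provenance = prov)
}

#' Read and validate a run configuration
#'
#' Configurations are YAML with a fixed key schema; unknown keys fail fast.
#'
#' @param path YAML file.
#' @return Validated configuration list with a `fingerprint` attribute.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("input", "format", "preprocess", "model", "kernel",
               "temperature", "background", "backend", "candidates", "seed",
               "output_dir")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  kernel_allowed <- c("family", "bandwidth", "blocks")
  if (!is.null(cfg$kernel)) {
    bad <- setdiff(names(cfg$kernel), kernel_allowed)
    if (length(bad)) stop("unknown kernel keys: ", paste(bad, collapse = ", "))
  }
  bg_allowed <- c("mode", "m_const", "c_b", "alpha", "nu", "D")
  if (!is.null(cfg$background)) {
    bad <- setdiff(names(cfg$background), bg_allowed)
    if (length(bad)) stop("unknown background keys: ",
                          paste(bad, collapse = ", "))
  }
  attr(cfg, "fingerprint") <- config_fingerprint(cfg)
  cfg
}

config_kernel <- function(cfg) {
  k <- cfg$kernel %||% list()
  kernel_spec(k$family %||% "rbf", k$bandwidth %||% "median",
              k$blocks %||% NULL)
}

config_policy <- function(cfg) {
  b <- cfg$background %||% list(mode = "pitman_yor")
  do.call(background_policy, b)
}
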