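# Persistence: bit-packed binary matrices with JSON sidecars, run
# tables, and PGM image export.

#' Save / load a binary matrix in bit-packed form
#'
#' The matrix is stored column-major as a packed bit stream (8 entries
#' per byte, via [packBits()]), alongside a JSON sidecar
#' (`<path>.json`) holding the dimensions, density, role, optional seed
#' and a schema version.  A 25,000 x 39,000 weight matrix packs into
#' about 122 MB.  Round trips are bit-exact.
#'
#' @param x matrix with entries in \{0, 1\} (numeric, integer or
#'   logical).
#' @param path destination file for the packed payload.
#' @param role free-text role tag (`"weights"`, `"mask"`, `"patterns"`,
#'   ...).
#' @param seed optional seed recorded in the metadata.
#' @return `path`, invisibly.
#' @export
save_matrix <- function(x, path, role = "matrix", seed = NA) {
  stopifnot(is.matrix(x))
  v <- as.logical(x)
  if (anyNA(v)) stop("matrix contains NA entries")
  pad <- (-length(v)) %% 8
  bits <- packBits(c(v, rep(FALSE, pad)), type = "raw")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(bits, con)
  meta <- list(schema = "btspcam-matrix/1", nrow = nrow(x), ncol = ncol(x),
               density = mean(v), role = role, seed = seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_matrix
#' @param mode storage mode of the returned matrix (`"integer"`,
#'   `"double"` or `"logical"`).
#' @return For `load_matrix`: the matrix, with the sidecar metadata
#'   attached as attribute `"meta"`.
#' @export
load_matrix <- function(path, mode = "integer") {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) stop("missing sidecar ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$schema, "btspcam-matrix/1"))
    stop("unsupported schema ", meta$schema %||% "<none>")
  nr <- meta$nrow; nc <- meta$ncol
  n_bytes <- ceiling(nr * nc / 8)
  raw <- readBin(path, what = "raw", n = n_bytes + 1)
  if (length(raw) < n_bytes) stop("payload truncated: ", path)
  v <- as.logical(rawToBits(raw[seq_len(n_bytes)]))[seq_len(nr * nc)]
  x <- matrix(v, nrow = nr, ncol = nc)
  storage.mode(x) <- mode
  attr(x, "meta") <- meta
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load an experiment run
#'
#' A run directory contains every result table as CSV plus a
#' `config.json` with the parameters, seed and schema version.
#'
#' @param tables named list of data frames.
#' @param dir destination directory (created if needed).
#' @param config named list of parameters to record.
#' @return `dir`, invisibly.
#' @export
save_run <- function(tables, dir, config = list()) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(tables))
    utils::write.csv(tables[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  config$schema <- "btspcam-run/1"
  config$tables <- names(tables)
  jsonlite::write_json(config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_run
#' @return For `load_run`: a list with `config` and the tables.
#' @export
load_run <- function(dir) {
  cfg_path <- file.path(dir, "config.json")
  if (!file.exists(cfg_path)) stop("not a run directory: ", dir)
  config <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  if (!identical(config$schema, "btspcam-run/1"))
    stop("unsupported run schema")
  tables <- lapply(config$tables, function(nm)
    utils::read.csv(file.path(dir, paste0(nm, ".csv"))))
  names(tables) <- config$tables
  c(list(config = config), tables)
}

#' Write / read a PGM image
#'
#' Plain-text (P2) portable graymap export for line-drawing patterns.
#'
#' @param img matrix of pixel values, or a flattened row-major vector
#'   (`side` then gives the canvas width).
#' @param path destination file.
#' @param maxval maximum gray value (1 for binary drawings).
#' @param side canvas side used to reshape flattened vectors.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path, maxval = 1, side = 50) {
  if (!is.matrix(img)) img <- matrix(img, nrow = side, byrow = TRUE)
  lines <- c("P2", paste(ncol(img), nrow(img)), as.character(maxval),
             apply(img, 1, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pgm
#' @return For `read_pgm`: the image matrix.
#' @export
read_pgm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (lines[1] != "P2") stop("only plain (P2) PGM is supported")
  dims <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  vals <- as.integer(unlist(strsplit(trimws(lines[-(1:3)]), "\\s+")))
  matrix(vals, nrow = dims[2], ncol = dims[1], byrow = TRUE)
}
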