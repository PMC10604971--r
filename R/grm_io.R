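#' Write / read a relationship matrix in GCTA binary format
#'
#' `write_grm()` writes three files sharing `prefix`: `.grm.bin` (row-major
#' lower triangle including the diagonal, 4-byte little-endian floats),
#' `.grm.id` (two tab-separated columns, family and individual id; the sample
#' id is used for both) and `.grm.json` (label, normalizer, method).
#' `read_grm()` inverts it up to float32 quantization (~1e-7 relative).
#'
#' @param g A [grm()].
#' @param prefix Path prefix (no extension).
#' @return `write_grm()`: `prefix` invisibly.  `read_grm()`: a `grm`.
#' @export
write_grm <- function(g, prefix) {
  stopifnot(inherits(g, "grm"))
  n <- nrow(g$matrix)
  lower <- g$matrix[upper.tri(g$matrix, diag = TRUE)] # column-major upper
  # GCTA stores row-major lower triangle == column-major upper triangle
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.numeric(lower), con, size = 4L, endian = "little")
  utils::write.table(data.frame(fid = g$sample_ids, iid = g$sample_ids),
                     paste0(prefix, ".grm.id"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(label = g$label, normalizer = g$normalizer, method = g$method,
         n = n),
    paste0(prefix, ".grm.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_grm
#' @export
read_grm <- function(prefix) {
  idf <- paste0(prefix, ".grm.id")
  binf <- paste0(prefix, ".grm.bin")
  metaf <- paste0(prefix, ".grm.json")
  if (!file.exists(idf)) stop("missing id sidecar: ", idf)
  ids <- utils::read.table(idf, sep = "\t", stringsAsFactors = FALSE)
  n <- nrow(ids)
  ntri <- n * (n + 1L) / 2L
  fsize <- file.info(binf)$size
  if (is.na(fsize) || fsize != 4L * ntri)
    stop("GRM binary ", binf, " has ", fsize, " bytes; expected ",
         4L * ntri, " for n = ", n, " (truncated or id mismatch)")
  con <- file(binf, "rb")
  on.exit(close(con), add = TRUE)
  vals <- readBin(con, "numeric", n = ntri, size = 4L, endian = "little")
  M <- matrix(0, n, n)
  M[upper.tri(M, diag = TRUE)] <- vals
  M <- M + t(M) - diag(diag(M))
  meta <- if (file.exists(metaf)) jsonlite::read_json(metaf) else
    list(label = "A", normalizer = NA, method = "first_order")
  if (!is.null(meta$n) && meta$n != n)
    stop("metadata sidecar records n = ", meta$n, " but id file has ", n)
  nrm <- if (is.null(meta$normalizer)) NA_real_ else as.numeric(meta$normalizer)
  grm(meta$label, M, ids[[2L]], normalizer = nrm, method = meta$method)
}
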