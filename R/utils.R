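# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

# Stable digest of an arbitrary R object: canonical deparse written to a
# temp file and md5-summed. Used for corpus digests and config hashes so that
# manifests are reproducible without a dedicated hashing dependency.
object_digest <- function(x) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf), add = TRUE)
  writeLines(deparse(x, control = c("keepNA", "keepInteger", "showAttributes")),
             tf, useBytes = TRUE)
  unname(tools::md5sum(tf))
}

# Read a text file that may or may not be gzip-compressed; gzfile() handles
# both transparently.
read_text_lines <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- gzfile(path, open = "rt")
  on.exit(close(con), add = TRUE)
  readLines(con, warn = FALSE)
}

# Key used everywhere a (domain, GO) pair indexes a map. "\r" cannot occur in
# either identifier, so the pasting is collision-free.
pair_key <- function(domain_id, go_id) paste(domain_id, go_id, sep = "\r")

# Deterministic TSV writer (no quoting, no row names).
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    comment.char = "", quote = "", check.names = FALSE)
}
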