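# FASTQ pairing rule: IDs are compared up to the first whitespace with a
# trailing /1 or /2 stripped.
normalize_read_id <- function(id) {
  id <- sub("\\s.*$", "", id)
  sub("/[12]$", "", id)
}

read_fastq_file <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  con <- gzfile(path, "rt") # reads plain and gzip transparently
  on.exit(close(con))
  lines <- readLines(con)
  n <- length(lines)
  if (n %% 4 != 0)
    stop("malformed FASTQ '", path, "': ", n,
         " lines is not a multiple of 4 (truncated record near line ", n, ")")
  if (n == 0)
    return(data.frame(id = character(), seq = character(), qual = character(),
                      stringsAsFactors = FALSE))
  hdr <- lines[seq(1, n, 4)]
  seq <- lines[seq(2, n, 4)]
  plus <- lines[seq(3, n, 4)]
  qual <- lines[seq(4, n, 4)]
  bad <- which(substr(hdr, 1, 1) != "@")
  if (length(bad))
    stop("malformed FASTQ '", path, "': header does not start with '@' at line ",
         (bad[1] - 1) * 4 + 1)
  bad <- which(substr(plus, 1, 1) != "+")
  if (length(bad))
    stop("malformed FASTQ '", path, "': separator does not start with '+' at line ",
         (bad[1] - 1) * 4 + 3)
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad))
    stop("malformed FASTQ '", path, "': sequence and quality lengths differ at line ",
         (bad[1] - 1) * 4 + 2)
  data.frame(id = substring(hdr, 2), seq = seq, qual = qual,
             stringsAsFactors = FALSE)
}

#' Read synchronized paired FASTQ files
#'
#' Reads two 4-line-record FASTQ files (plain or gzip, detected
#' transparently) and validates that they are synchronized: equal record
#' counts and matching identifiers after `/1`, `/2` normalization.
#'
#' @param path1,path2 paths to the R1 and R2 FASTQ files.
#' @return a `data.frame` with columns `id1`, `seq1`, `qual1`, `id2`,
#'   `seq2`, `qual2`, one row per pair.
#' @export
read_fastq_pairs <- function(path1, path2) {
  a <- read_fastq_file(path1)
  b <- read_fastq_file(path2)
  if (nrow(a) != nrow(b))
    stop("desynchronized FASTQ inputs: ", nrow(a), " vs ", nrow(b),
         " records (first missing mate at pair ", min(nrow(a), nrow(b)) + 1, ")")
  if (nrow(a)) {
    ida <- normalize_read_id(a$id)
    idb <- normalize_read_id(b$id)
    bad <- which(ida != idb)
    if (length(bad))
      stop("desynchronized FASTQ inputs: identifiers disagree at pair ",
           bad[1], " ('", a$id[bad[1]], "' vs '", b$id[bad[1]], "')")
  }
  data.frame(id1 = a$id, seq1 = a$seq, qual1 = a$qual,
             id2 = b$id, seq2 = b$seq, qual2 = b$qual,
             stringsAsFactors = FALSE)
}

write_fastq_file <- function(id, seq, qual, path, compress = FALSE) {
  con <- if (compress) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  n <- length(id)
  out <- character(4 * n)
  if (n) {
    out[seq(1, 4 * n, 4)] <- paste0("@", id)
    out[seq(2, 4 * n, 4)] <- seq
    out[seq(3, 4 * n, 4)] <- "+"
    out[seq(4, 4 * n, 4)] <- qual
  }
  writeLines(out, con)
  invisible(path)
}

#' Write paired FASTQ files
#'
#' Writes byte-stable 4-line records; with `compress = TRUE` the outputs are
#' gzip streams.
#'
#' @param pairs a `data.frame` as returned by [read_fastq_pairs()].
#' @param out1,out2 output paths.
#' @param compress write gzip-compressed outputs (default: `TRUE` when the
#'   output path ends in `.gz`).
#' @return invisibly, a list with the record count written.
#' @export
write_fastq_pairs <- function(pairs, out1, out2,
                              compress = grepl("\\.gz$", out1)) {
  write_fastq_file(pairs$id1, pairs$seq1, pairs$qual1, out1, compress)
  write_fastq_file(pairs$id2, pairs$seq2, pairs$qual2, out2, compress)
  invisible(list(pairs_written = nrow(pairs)))
}
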