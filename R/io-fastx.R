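#' Read FASTA/FASTQ into read records
#'
#' Streams a FASTA or FASTQ file (plain or gzipped; format sniffed from
#' the first non-empty byte) into a read-record data.frame. Multi-line
#' FASTA is supported; FASTQ records are strict 4-line. Sequences are
#' uppercased on ingestion. Malformed files are reported with the 1-based
#' index of the offending record.
#'
#' Parsing is delegated to Biostrings; on failure a lightweight
#' diagnostic scan locates the first malformed record.
#'
#' @param path FASTA/FASTQ file, optionally `.gz`.
#' @return data.frame with columns `seq_id` (header up to first
#'   whitespace), `description` (remainder, possibly ""), `sequence`, and
#'   `quality` (NA for FASTA).
#' @export
read_fastx <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  fmt <- sniff_fastx_format(path)
  if (fmt == "fastq") validate_fastq(path)
  res <- tryCatch(
    if (fmt == "fasta") {
      x <- Biostrings::readDNAStringSet(path, format = "fasta")
      list(headers = names(x), seqs = as.character(x),
           quals = rep(NA_character_, length(x)))
    } else {
      x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
      list(headers = names(x), seqs = as.character(x),
           quals = as.character(Biostrings::quality(x)))
    },
    error = function(e) e)
  if (inherits(res, "error")) diagnose_fastx(path, fmt, conditionMessage(res))
  bad <- which(!is.na(res$quals) &
               nchar(res$quals, type = "bytes") !=
                 nchar(res$seqs, type = "bytes"))
  if (length(bad))
    stop("record ", bad[1], " in ", path,
         ": quality and sequence lengths differ")
  id <- sub("\\s.*$", "", res$headers)
  desc <- ifelse(grepl("\\s", res$headers),
                 sub("^\\S+\\s+", "", res$headers), "")
  data.frame(seq_id = id, description = desc,
             sequence = toupper(res$seqs), quality = res$quals,
             stringsAsFactors = FALSE)
}

sniff_fastx_format <- function(path) {
  con <- open_text(path, "rt")
  on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) stop("empty file: ", path)
    ln <- sub("\r$", "", ln)
    if (nzchar(ln)) {
      c1 <- substr(ln, 1L, 1L)
      if (c1 == ">") return("fasta")
      if (c1 == "@") return("fastq")
      stop("cannot sniff format of ", path,
           ": first record starts with '", c1, "', expected '>' or '@'")
    }
  }
}

# Strict structural validation of 4-line FASTQ records; errors carry the
# 1-based index of the first malformed record. Run before parsing because
# permissive parsers do not reliably reject these defects.
validate_fastq <- function(path) {
  con <- open_text(path, "rt")
  on.exit(close(con))
  lines <- sub("\r$", "", readLines(con))
  lines <- lines[nzchar(lines) | seq_along(lines) %% 4L != 1L]
  n <- length(lines)
  for (i in seq_len(ceiling(n / 4))) {
    rec <- lines[(4L * (i - 1L) + 1L):min(4L * i, n)]
    why <- NULL
    if (length(rec) < 4L) why <- "incomplete 4-line record"
    else if (!startsWith(rec[1], "@")) why <- "header does not start with '@'"
    else if (!startsWith(rec[3], "+")) why <- "separator line does not start with '+'"
    else if (nchar(rec[2], type = "bytes") != nchar(rec[4], type = "bytes"))
      why <- "quality and sequence lengths differ"
    if (!is.null(why)) stop("record ", i, " in ", path, ": ", why)
  }
  invisible(n %/% 4L)
}

# Locate the first malformed record and report its 1-based index.
diagnose_fastx <- function(path, fmt, parent_msg) {
  con <- open_text(path, "rt")
  on.exit(close(con))
  lines <- sub("\r$", "", readLines(con))
  if (fmt == "fasta") {
    lines <- lines[nzchar(lines)]
    if (length(lines) && !startsWith(lines[1], ">"))
      stop("record 1 in ", path, ": leading sequence without '>' header")
    bad <- grep("[^ACGTNacgtn]", lines[!startsWith(lines, ">")])
    if (length(bad)) {
      rec <- findInterval(which(!startsWith(lines, ">"))[bad[1]],
                          which(startsWith(lines, ">")))
      stop("record ", rec, " in ", path, ": invalid sequence character")
    }
  }
  stop("malformed ", fmt, " file ", path, ": ", parent_msg)
}

#' Write read records as FASTA/FASTQ, optionally with annotations
#'
#' Writes records in input order, FASTQ when qualities are present (and
#' `format` allows), FASTA otherwise; `.gz` paths are compressed. When an
#' annotation data.frame is supplied (matched to records by `seq_id`),
#' each header carries the classifier fields in fixed order:
#' `SeqId ReadLen=<int> isConsecutiveMatchFound=<0|1>
#' AnchorProportion=<4 decimals>`.
#'
#' @param records read-record data.frame ([read_fastx()] layout).
#' @param path output file.
#' @param annotations optional annotation data.frame from the classifier.
#' @param format `"auto"` mirrors the input records.
#' @return number of records written, invisibly.
#' @export
write_fastx <- function(records, path, annotations = NULL,
                        format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  n <- nrow(records)
  has_q <- n > 0 && !anyNA(records$quality)
  if (format == "auto") format <- if (has_q) "fastq" else "fasta"
  if (format == "fastq" && !has_q)
    stop("cannot write FASTQ: records carry no qualities")
  headers <- records$seq_id
  if (!is.null(annotations)) {
    i <- match(records$seq_id, annotations$seq_id)
    if (anyNA(i)) stop("annotations missing for some records")
    a <- annotations[i, , drop = FALSE]
    headers <- sprintf("%s ReadLen=%d isConsecutiveMatchFound=%d AnchorProportion=%.4f",
                       records$seq_id, a$read_len,
                       as.integer(a$is_consecutive_match_found),
                       a$anchor_proportion)
  } else if (n > 0 && any(nzchar(records$description))) {
    headers <- ifelse(nzchar(records$description),
                      paste(records$seq_id, records$description),
                      records$seq_id)
  }
  con <- open_text(path, "wt")
  on.exit(close(con))
  if (n > 0) {
    if (format == "fastq")
      writeLines(rbind(paste0("@", headers), records$sequence, "+",
                       records$quality), con)
    else
      writeLines(rbind(paste0(">", headers), records$sequence), con)
  }
  invisible(n)
}

#' Parse classifier fields out of an annotated header description
#'
#' Inverse of the header dialect written by [write_fastx()]: whitespace
#' separated `key=value` fields.
#'
#' @param description character vector of header descriptions.
#' @return data.frame with `read_len`, `is_consecutive_match_found`,
#'   `anchor_proportion`.
#' @export
parse_annotation_fields <- function(description) {
  get_field <- function(key, desc)
    sub(paste0("^.*", key, "=(\\S+).*$"), "\\1", desc)
  data.frame(
    read_len = as.integer(get_field("ReadLen", description)),
    is_consecutive_match_found =
      as.integer(get_field("isConsecutiveMatchFound", description)) == 1L,
    anchor_proportion = as.numeric(get_field("AnchorProportion", description)),
    stringsAsFactors = FALSE)
}

#' Write / read the per-read annotation table (TSV sidecar)
#'
#' One row per input read (retained and discarded), for evaluation.
#'
#' @param annotations annotation data.frame.
#' @param path TSV path, optionally `.gz`.
#' @return `read_annotations` returns the data.frame.
#' @export
write_annotations <- function(annotations, path) {
  out <- annotations
  out$is_consecutive_match_found <-
    as.integer(out$is_consecutive_match_found)
  out$retained <- as.integer(out$retained)
  con <- open_text(path, "wt")
  on.exit(close(con))
  write.table(format(out, digits = 6, scientific = FALSE, trim = TRUE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$is_consecutive_match_found <- df$is_consecutive_match_found == 1L
  df$retained <- df$retained == 1L
  df$seq_id <- as.character(df$seq_id)
  df
}
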