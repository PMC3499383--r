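#' Construct a prohormone record
#'
#' A `prohormone_record` bundles a protein sequence with its cleavage
#' annotation: the set of P1 positions (1-based) after which the precursor
#' is cut, plus an optional N-terminal signal-peptide length. Every cleaved
#' position must carry a basic residue (K or R) — the substrate convention
#' of prohormone convertases.
#'
#' @param id Record identifier (single string, no whitespace).
#' @param sequence Amino-acid string over the 20-letter alphabet plus `X`
#'   for unknown residues. Lowercase input is uppercased.
#' @param cleaved_positions Integer vector of 1-based P1 positions
#'   (cleavage occurs C-terminal to each). May be empty.
#' @param signal_length Optional non-negative signal-peptide length
#'   (`NA` when unknown/absent).
#' @param strict If `TRUE` (default) a cleaved position on a non-K/R
#'   residue is an error; if `FALSE` it is kept with a warning.
#' @return An object of class `prohormone_record`.
#' @examples
#' prohormone_record("toy1", "MAKRSA", cleaved_positions = 4)
#' @export
prohormone_record <- function(id, sequence, cleaved_positions = integer(),
                              signal_length = NA_integer_, strict = TRUE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(as.character(sequence))
  bad <- setdiff(strsplit(sequence, "")[[1]], AA21)
  if (length(bad) > 0L) {
    stop("record '", id, "': illegal residue character(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  n <- nchar(sequence)
  pos <- sort(unique(as.integer(cleaved_positions)))
  if (any(pos < 1L | pos > n)) {
    stop("record '", id, "': cleaved position outside sequence", call. = FALSE)
  }
  res <- if (length(pos) > 0L) substring(sequence, pos, pos) else character(0)
  nonbasic <- pos[!res %in% c("K", "R")]
  if (length(nonbasic) > 0L) {
    msg <- paste0("record '", id, "': cleaved position(s) ",
                  paste(nonbasic, collapse = ", "),
                  " not on a K/R residue")
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  if (!is.na(signal_length)) {
    signal_length <- as.integer(signal_length)
    if (signal_length < 0L || signal_length >= n) {
      stop("record '", id, "': signal_length must be in [0, sequence length)",
           call. = FALSE)
    }
  }
  structure(list(id = id, sequence = sequence, cleaved_positions = pos,
                 signal_length = signal_length),
            class = "prohormone_record")
}

#' @export
print.prohormone_record <- function(x, ...) {
  cat("<prohormone_record> ", x$id, ": ", nchar(x$sequence), " aa, ",
      length(x$cleaved_positions), " cleaved site(s)",
      if (!is.na(x$signal_length)) paste0(", signal ", x$signal_length, " aa"),
      "\n", sep = "")
  invisible(x)
}

# Header grammar: ">id" optionally followed by " [signal=N]".
parse_annot_header <- function(line) {
  body <- sub("^>", "", line)
  signal <- NA_integer_
  m <- regmatches(body, regexec("\\[signal=([0-9]+)\\]", body))[[1]]
  if (length(m) == 2L) {
    signal <- as.integer(m[2])
    body <- sub("\\s*\\[signal=[0-9]+\\]", "", body)
  }
  id <- strsplit(trimws(body), "\\s+")[[1]][1]
  list(id = id, signal = signal)
}

#' Read annotated prohormone sequences
#'
#' Reads the plain-text annotation dialect documented in `ANNOT.md`: each
#' record is a FASTA-style header `>id [signal=N]` followed by sequence
#' lines paired with annotation lines of `.` (candidate position, not
#' cleaved or not a candidate) and `|` (cleaved, written under the P1
#' residue). Sequence and annotation tracks must have equal total length.
#'
#' @param path Path to an annotated file.
#' @param strict If `TRUE` (default) a `|` under a non-K/R residue is a
#'   validation error; if `FALSE` it is downgraded to a warning and the
#'   annotation retained.
#' @return A list of [prohormone_record] objects, in file order.
#' @seealso [write_annotated()] for the inverse; [read_fasta()] for
#'   unannotated input.
#' @export
read_annotated <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty annotation file: ", path, call. = FALSE)
    return(list())
  }
  starts <- grep("^>", lines)
  if (length(starts) == 0L || starts[1] != 1L) {
    stop("malformed annotation file (no leading '>' header): ", path,
         call. = FALSE)
  }
  ends <- c(starts[-1] - 1L, length(lines))
  records <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    hdr <- parse_annot_header(lines[starts[k]])
    body <- lines[seq(starts[k] + 1L, length.out = ends[k] - starts[k])]
    is_annot <- grepl("^[.|]+$", body)
    is_seq <- grepl("^[A-Za-z]+$", body)
    if (any(!is_annot & !is_seq)) {
      stop("record '", hdr$id, "': line with illegal characters: '",
           body[which(!is_annot & !is_seq)[1]], "'", call. = FALSE)
    }
    seq <- paste(body[is_seq], collapse = "")
    ann <- paste(body[is_annot], collapse = "")
    if (nchar(seq) != nchar(ann)) {
      stop("record '", hdr$id, "': sequence length (", nchar(seq),
           ") and annotation length (", nchar(ann), ") differ",
           call. = FALSE)
    }
    cleaved <- which(strsplit(ann, "")[[1]] == "|")
    records[[k]] <- prohormone_record(hdr$id, seq, cleaved,
                                      signal_length = hdr$signal,
                                      strict = strict)
  }
  records
}

#' Write annotated prohormone sequences
#'
#' Emits the annotation dialect read by [read_annotated()]: 60 residues per
#' line, each sequence line followed by its aligned annotation line.
#' `read_annotated()` followed by `write_annotated()` reproduces a
#' canonical file byte-identically.
#'
#' @param records List of [prohormone_record] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotated <- function(records, path) {
  if (inherits(records, "prohormone_record")) records <- list(records)
  out <- character(0)
  for (rec in records) {
    stopifnot(inherits(rec, "prohormone_record"))
    hdr <- paste0(">", rec$id,
                  if (!is.na(rec$signal_length))
                    paste0(" [signal=", rec$signal_length, "]"))
    n <- nchar(rec$sequence)
    ann <- rep(".", n)
    ann[rec$cleaved_positions] <- "|"
    ann <- paste(ann, collapse = "")
    from <- seq(1L, n, by = 60L)
    to <- pmin(from + 59L, n)
    pairs <- as.vector(rbind(substring(rec$sequence, from, to),
                             substring(ann, from, to)))
    out <- c(out, hdr, pairs)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Read unannotated protein FASTA
#'
#' Standard protein FASTA, parsed with Biostrings. Returned records carry
#' empty cleavage annotations (prediction-only use). Lowercase residues
#' are uppercased; characters outside the 20-letter alphabet plus `X` are
#' rejected.
#'
#' @param path Path to a FASTA file.
#' @return A list of [prohormone_record] objects with no cleaved positions.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  if (length(raw) == 0L || !any(grepl("^>", raw))) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(list())
  }
  seq_lines <- raw[!grepl("^>", raw)]
  if (any(grepl("[^A-Za-z[:space:]]", seq_lines))) {
    stop("illegal residue character in FASTA sequence: ", path,
         call. = FALSE)
  }
  aas <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aas), "\\s+"), `[`, character(1), 1L)
  lapply(seq_along(aas), function(i) {
    prohormone_record(ids[i], as.character(aas[[i]]))
  })
}
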