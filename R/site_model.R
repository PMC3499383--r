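#' Site-window configuration
#'
#' Controls how candidate cleavage sites are enumerated and how their
#' prediction windows are cut. The window covers `upstream` residues
#' ending at P1 (so P1 sits at window index `upstream`) and `downstream`
#' residues on the P' side; positions beyond the sequence termini are
#' filled with `pad_char`. `upstream >= 4` is required so the RxxR motif
#' (R at P4) is always visible.
#'
#' @param upstream Window length on the P side, P1 included (default 9).
#' @param downstream Window length on the P' side (default 9).
#' @param exclude_signal Drop candidate sites inside the annotated signal
#'   peptide (default `TRUE`): the signal is removed by signal peptidase,
#'   not by prohormone convertases.
#' @param pad_char Single character used beyond the termini (default "X").
#' @return An object of class `site_config`.
#' @export
site_config <- function(upstream = 9L, downstream = 9L,
                        exclude_signal = TRUE, pad_char = "X") {
  upstream <- as.integer(upstream)
  downstream <- as.integer(downstream)
  if (upstream < 4L) stop("upstream must be >= 4 (P4 must be in-window)",
                          call. = FALSE)
  if (downstream < 1L) stop("downstream must be >= 1", call. = FALSE)
  stopifnot(is.character(pad_char), nchar(pad_char) == 1L)
  structure(list(upstream = upstream, downstream = downstream,
                 exclude_signal = isTRUE(exclude_signal),
                 pad_char = pad_char),
            class = "site_config")
}

MOTIF_TAGS <- c("xxKR", "xxRR", "RxxR", "singleR", "other")

#' Tag a site window with the cleavage-motif taxonomy
#'
#' Motifs are defined by the residues at P1 (the basic residue the bond
#' follows), P2 and P4: `xxKR` = K at P2, R at P1; `xxRR` = R at P2, R at
#' P1; `RxxR` = R at P4, R at P1; `singleR` = R at P1 with no basic
#' residue at P2 or P4 (the monobasic class). Tags may co-occur (an RR
#' pair with R at P4 is both `xxRR` and `RxxR`); any site matching none —
#' including every K-at-P1 site without one of the patterns — is tagged
#' `other`, so each site carries at least one tag.
#'
#' @param window Site window string (P1 at index `upstream`).
#' @param upstream P-side window length used to cut `window`.
#' @return Character vector of tags (subset of
#'   `c("xxKR", "xxRR", "RxxR", "singleR", "other")`).
#' @export
classify_motif <- function(window, upstream = 9L) {
  if (upstream < 4L) stop("window must expose P4: upstream >= 4 required",
                          call. = FALSE)
  if (nchar(window) < upstream) stop("window shorter than upstream length",
                                     call. = FALSE)
  p1 <- substring(window, upstream, upstream)
  p2 <- substring(window, upstream - 1L, upstream - 1L)
  p4 <- substring(window, upstream - 3L, upstream - 3L)
  tags <- character(0)
  if (p2 == "K" && p1 == "R") tags <- c(tags, "xxKR")
  if (p2 == "R" && p1 == "R") tags <- c(tags, "xxRR")
  if (p4 == "R" && p1 == "R") tags <- c(tags, "RxxR")
  if (p1 == "R" && !p2 %in% c("K", "R") && !p4 %in% c("K", "R")) {
    tags <- c(tags, "singleR")
  }
  if (length(tags) == 0L) tags <- "other"
  tags
}

extract_window <- function(sequence, position, config) {
  n <- nchar(sequence)
  idx <- (position - config$upstream + 1L):(position + config$downstream)
  chars <- rep(config$pad_char, length(idx))
  inside <- idx >= 1L & idx <= n
  chars[inside] <- substring(sequence, idx[inside], idx[inside])
  paste(chars, collapse = "")
}

#' Enumerate candidate cleavage sites
#'
#' Every K or R residue is a candidate site (cleavage C-terminal to it);
#' candidates inside the annotated signal peptide are dropped when
#' `config$exclude_signal` is set. Each site gets its prediction window,
#' its observed label from the record's annotation, and its motif tags.
#'
#' @param records A [prohormone_record] or list of them.
#' @param config A [site_config].
#' @return A data frame with one row per candidate site, ordered by record
#'   then ascending 1-based `position`: columns `record_id`, `position`,
#'   `residue`, `window`, `cleaved` (logical) and one logical column per
#'   motif tag (`xxKR`, `xxRR`, `RxxR`, `singleR`, `other`).
#' @examples
#' rec <- prohormone_record("toy", "MKRAASRLL")
#' enumerate_sites(rec, site_config())
#' @export
enumerate_sites <- function(records, config = site_config()) {
  stopifnot(inherits(config, "site_config"))
  if (inherits(records, "prohormone_record")) records <- list(records)
  per_record <- lapply(records, function(rec) {
    stopifnot(inherits(rec, "prohormone_record"))
    chars <- strsplit(rec$sequence, "")[[1]]
    pos <- which(chars %in% c("K", "R"))
    if (config$exclude_signal && !is.na(rec$signal_length)) {
      pos <- pos[pos > rec$signal_length]
    }
    if (length(pos) == 0L) return(NULL)
    windows <- vapply(pos, function(p) extract_window(rec$sequence, p, config),
                      character(1))
    tags <- lapply(windows, classify_motif, upstream = config$upstream)
    df <- data.frame(record_id = rec$id, position = pos,
                     residue = chars[pos], window = windows,
                     cleaved = pos %in% rec$cleaved_positions,
                     stringsAsFactors = FALSE)
    for (tag in MOTIF_TAGS) {
      df[[tag]] <- vapply(tags, function(t) tag %in% t, logical(1))
    }
    df
  })
  per_record <- per_record[!vapply(per_record, is.null, logical(1))]
  if (length(per_record) == 0L) {
    df <- data.frame(record_id = character(), position = integer(),
                     residue = character(), window = character(),
                     cleaved = logical(), stringsAsFactors = FALSE)
    for (tag in MOTIF_TAGS) df[[tag]] <- logical(0)
    attr(df, "site_config") <- config
    return(df)
  }
  out <- do.call(rbind, per_record)
  rownames(out) <- NULL
  attr(out, "site_config") <- config
  out
}

#' Prevalence and motif statistics over candidate sites
#'
#' Prevalence is the proportion of candidate (possible) sites that are
#' cleaved. Motif frequencies are computed among cleaved sites only; tags
#' overlap, so frequencies need not sum to 1. The count of cleaved
#' monobasic (single-R) sites is reported separately.
#'
#' @param sites Candidate-site data frame from [enumerate_sites()].
#' @return A list of class `motif_stats`: `n_candidates`, `n_cleaved`,
#'   `prevalence`, `motif_freq` (named numeric over the five tags),
#'   `n_singleR_cleaved`.
#' @export
motif_statistics <- function(sites) {
  if (!is.data.frame(sites) || nrow(sites) == 0L) {
    stop("motif_statistics() needs a non-empty candidate-site table",
         call. = FALSE)
  }
  n <- nrow(sites)
  cle <- sites[sites$cleaved, , drop = FALSE]
  freq <- vapply(MOTIF_TAGS, function(tag) {
    if (nrow(cle) == 0L) NA_real_ else mean(cle[[tag]])
  }, numeric(1))
  structure(list(n_candidates = n, n_cleaved = nrow(cle),
                 prevalence = nrow(cle) / n,
                 motif_freq = freq,
                 n_singleR_cleaved = sum(cle$singleR)),
            class = "motif_stats")
}

#' @export
print.motif_stats <- function(x, ...) {
  cat("<motif_stats>\n",
      "  candidate sites: ", x$n_candidates, "\n",
      "  cleaved sites:   ", x$n_cleaved, "\n",
      "  prevalence:      ", sprintf("%.4f", x$prevalence), "\n", sep = "")
  cat("  motif frequency among cleaved (overlapping tags):\n")
  for (tag in names(x$motif_freq)) {
    cat(sprintf("    %-8s %s\n", tag,
                ifelse(is.na(x$motif_freq[[tag]]), "undefined",
                       sprintf("%.4f", x$motif_freq[[tag]]))))
  }
  cat("  cleaved single-R sites: ", x$n_singleR_cleaved, "\n", sep = "")
  invisible(x)
}
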