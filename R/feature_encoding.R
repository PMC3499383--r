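#' Load a physicochemical property table
#'
#' Reads a tab-separated table (rows = the 20 standard residues, columns =
#' named per-residue scales), z-score standardises every scale over the 20
#' residues, and appends an all-zero row for `X` (pad/unknown is neutral
#' after standardisation). The default table ships five classical scales:
#' Kyte-Doolittle hydropathy, residue volume (A^3), net charge at pH 7,
#' Grantham polarity, and Chou-Fasman helix propensity.
#'
#' @param path Path to a property TSV; defaults to the table shipped with
#'   the package.
#' @return A numeric matrix of class `property_table`, 21 rows (residues
#'   `A`..`Y` plus `X`) by one column per scale, standardised.
#' @export
load_property_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aa_properties.tsv", package = "procleave",
                        mustWork = TRUE)
  }
  raw <- read.delim(path, stringsAsFactors = FALSE)
  if (!identical(sort(raw$residue), sort(AA20))) {
    stop("property table must cover exactly the 20 standard residues",
         call. = FALSE)
  }
  vals <- as.matrix(raw[, setdiff(names(raw), "residue"), drop = FALSE])
  rownames(vals) <- raw$residue
  vals <- vals[AA20, , drop = FALSE]
  vals <- scale(vals)                      # z-score over the 20 residues
  vals <- rbind(vals, X = rep(0, ncol(vals)))
  attr(vals, "scaled:center") <- NULL
  attr(vals, "scaled:scale") <- NULL
  class(vals) <- c("property_table", class(vals))
  vals
}

window_chars <- function(windows) {
  m <- matrix(unlist(strsplit(windows, "")), nrow = length(windows),
              byrow = TRUE)
  bad <- matrix(!(m %in% AA21), nrow = nrow(m))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, , drop = TRUE]
    stop("unknown character '", m[bad][1], "' at window position ",
         idx[["col"]], call. = FALSE)
  }
  m
}

#' Encode site windows as numeric feature vectors
#'
#' Two schemes: `"AA"` is a per-position one-hot over the 21-symbol
#' alphabet (20 residues + `X`); `"AA_PROP"` appends, after each
#' position's one-hot block, that position's standardised physicochemical
#' property values. Layout is window-position-major, so two windows that
#' differ at a single position differ only within that position's block.
#'
#' @param windows Character vector of equal-length windows.
#' @param scheme `"AA"` or `"AA_PROP"`.
#' @param table A `property_table` (required for `"AA_PROP"`; the shipped
#'   default is used when `NULL`).
#' @return A numeric matrix, one row per window; columns named
#'   `p<i>.<symbol>` and `p<i>.<scale>`. Attribute `scheme` records the
#'   encoding.
#' @export
encode_windows <- function(windows, scheme = c("AA", "AA_PROP"),
                           table = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(length(windows) > 0L)
  if (length(unique(nchar(windows))) != 1L) {
    stop("all windows must have equal length", call. = FALSE)
  }
  w <- nchar(windows[1])
  chars <- window_chars(windows)
  if (scheme == "AA_PROP" && is.null(table)) table <- load_property_table()
  blocks <- lapply(seq_len(w), function(j) {
    onehot <- outer(chars[, j], AA21, "==") * 1
    colnames(onehot) <- paste0("p", j, ".", AA21)
    if (scheme == "AA") return(onehot)
    props <- table[chars[, j], , drop = FALSE]
    colnames(props) <- paste0("p", j, ".", colnames(table))
    cbind(onehot, props)
  })
  out <- do.call(cbind, blocks)
  rownames(out) <- NULL
  attr(out, "scheme") <- scheme
  attr(out, "window_len") <- w
  out
}

#' Encode candidate sites under a model's feature scheme
#'
#' Convenience wrapper: extracts the `window` column of a candidate-site
#' table from [enumerate_sites()] and calls [encode_windows()].
#'
#' @inheritParams encode_windows
#' @param sites Candidate-site data frame.
#' @return Feature matrix, one row per site.
#' @export
encode_sites <- function(sites, scheme = c("AA", "AA_PROP"), table = NULL) {
  stopifnot(is.data.frame(sites), "window" %in% names(sites))
  encode_windows(sites$window, scheme = scheme, table = table)
}
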