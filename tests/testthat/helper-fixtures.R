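# Shared fixtures: all built in code at test time.

# Write an annotated-dialect file from raw lines and return its path
# (session tempdir; cleaned up when the test session exits).
write_annot_lines <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}

toy_annot_file <- function() {
  write_annot_lines(c(">toy1", "MAKRSA", "...|.."))
}

# Build a candidate-site table directly from windows (bypasses sequence
# assembly) for model unit tests; window layout matches site_config().
make_site_table <- function(windows, cleaved, upstream = 9L,
                            downstream = 9L) {
  stopifnot(all(nchar(windows) == upstream + downstream))
  cfg <- site_config(upstream = upstream, downstream = downstream)
  df <- data.frame(record_id = sprintf("w%03d", seq_along(windows)),
                   position = rep(upstream, length(windows)),
                   residue = substring(windows, upstream, upstream),
                   window = windows, cleaved = cleaved,
                   stringsAsFactors = FALSE)
  tags <- lapply(windows, classify_motif, upstream = upstream)
  for (tag in c("xxKR", "xxRR", "RxxR", "singleR", "other")) {
    df[[tag]] <- vapply(tags, function(t) tag %in% t, logical(1))
  }
  attr(df, "site_config") <- cfg
  df
}

# Window with given residues at P4/P2/P1 and 'A' elsewhere (9+9 layout).
window_p421 <- function(p4 = "A", p2 = "A", p1 = "R", fill = "A") {
  chars <- rep(fill, 18)
  chars[6] <- p4; chars[8] <- p2; chars[9] <- p1
  paste(chars, collapse = "")
}

# A linearly separable toy set: cleaved iff P1 == 'R'.
separable_sites <- function(n_each = 12L) {
  wins <- c(replicate(n_each, window_p421(p1 = "R", fill = sample(c("A", "G", "S"), 1))),
            replicate(n_each, window_p421(p1 = "K", fill = sample(c("A", "G", "S"), 1))))
  make_site_table(wins, cleaved = rep(c(TRUE, FALSE), each = n_each))
}
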