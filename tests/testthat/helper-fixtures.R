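# Programmatic fixtures: small MaxQuant-style tables written to tempfiles.

write_pg_fixture <- function(n_channels = 10L, path = tempfile(fileext = ".txt")) {
  n <- 10L
  set.seed(99)
  tab <- data.frame(
    `Majority protein IDs` = c(sprintf("PRT%02d;ALT%02d", 1:9, 1:9), "CON__PRT10"),
    `Gene names` = sprintf("Gene%02d", 1:10),
    `Unique peptides` = c(1L, rep(5L, 9L)),
    `MS/MS count` = rep(20L, 10L),
    `Potential contaminant` = c(rep("", 9L), "+"),
    `Reverse` = c("+", rep("", 9L)),
    `Only identified by site` = c("", "+", rep("", 8L)),
    check.names = FALSE, stringsAsFactors = FALSE)
  for (k in seq_len(n_channels)) {
    v <- round(runif(n, 1e5, 1e7))
    v[1L + (k %% n)] <- 0  # one non-detection per channel
    tab[[sprintf("Reporter intensity corrected %d", k)]] <- v
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

pg_channel_map <- function(n_channels = 10L) {
  data.frame(column = sprintf("Reporter intensity corrected %d", seq_len(n_channels)),
             label = sprintf("ch%d", seq_len(n_channels)),
             condition = rep(c("A", "B"), each = ceiling(n_channels / 2))[seq_len(n_channels)],
             stringsAsFactors = FALSE)
}

write_sites_fixture <- function(path = tempfile(fileext = ".txt")) {
  tab <- data.frame(
    Protein = c("PRT01", "PRT01", "PRT02", "REV__PRT03"),
    `Amino acid` = c("S", "S", "T", "Y"),
    Position = c(15L, 15L, 77L, 3L),
    Multiplicity = c(1L, 2L, 1L, 1L),
    `Gene names` = c("GeneA", "GeneA", "GeneB", "GeneC"),
    Reverse = c("", "", "", "+"),
    check.names = FALSE, stringsAsFactors = FALSE)
  for (k in 1:4)
    tab[[sprintf("Reporter intensity corrected %d", k)]] <- round(runif(4, 1e4, 1e6))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Noise-free 4PL responses on the secondary-screen 10-point dose ladder (M).
secondary_screen_ladder <- function() {
  c(4.0e-5, 1.3e-5, 4.0e-6, 1.3e-6, 4.0e-7, 1.3e-7, 4.0e-8, 1.3e-8, 4.0e-9, 1.3e-9)
}

fourpl <- function(x, bottom, top, ec50, hill) {
  bottom + (top - bottom) / (1 + (ec50 / x)^hill)
}
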