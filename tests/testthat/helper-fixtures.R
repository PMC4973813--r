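random_gm <- function(n_lines = 20, n_markers = 50, nc_rate = 0.05,
                      p = 0.5, seed = 1) {
  set.seed(seed)
  calls <- matrix(sample(c("AA", "AB", "BB"), n_lines * n_markers, TRUE,
                         prob = c(p^2, 2 * p * (1 - p), (1 - p)^2)),
                  nrow = n_lines,
                  dimnames = list(sprintf("L%02d", 1:n_lines),
                                  sprintf("M%03d", 1:n_markers)))
  calls[runif(length(calls)) < nc_rate] <- "NC"
  fabmap::genotype_matrix(calls)
}

# a simple evenly spaced true map
toy_map <- function(n_groups = 2, markers_per_group = 10, spacing_cm = 10) {
  do.call(rbind, lapply(seq_len(n_groups), function(g) {
    data.frame(marker = sprintf("G%dM%02d", g, seq_len(markers_per_group)),
               group = paste0("chr", g),
               position_cM = (seq_len(markers_per_group) - 1) * spacing_cm,
               stringsAsFactors = FALSE)
  }))
}
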