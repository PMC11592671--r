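# Independent reference implementations used to cross-check package results.

# Per-window CRM1 class assignment via regular expressions (precedence
# 1a > 1b > 2 > 3, Phi = L/I/V/F/M, Ala tolerated at the first slot only,
# pattern may sit anywhere inside the window).
oracle_crm1_class <- function(window) {
  pats <- c(
    "1a" = "[LIVFMA].{3}[LIVFM].{2}[LIVFM].[LIVFM]",
    "1b" = "[LIVFMA].{2}[LIVFM].{2}[LIVFM].[LIVFM]",
    "2"  = "[LIVFMA].[LIVFM].{2}[LIVFM].[LIVFM]",
    "3"  = "[LIVFMA].{2}[LIVFM].{3}[LIVFM].[LIVFM]"
  )
  for (cls in names(pats)) if (grepl(pats[[cls]], window)) return(cls)
  "none"
}

# Brute-force NES scan: classify every window, then merge overlapping
# same-class windows by interval union (overlap means start gap < window).
oracle_nes_hits <- function(residues, window = 15L) {
  n <- nchar(residues)
  starts <- integer(); classes <- character()
  if (n >= window) {
    for (i in seq_len(n - window + 1L)) {
      cls <- oracle_crm1_class(substr(residues, i, i + window - 1L))
      if (cls != "none") { starts <- c(starts, i); classes <- c(classes, cls) }
    }
  }
  out <- data.frame(start = integer(), end = integer(), class = character())
  for (cls in unique(classes)) {
    s <- sort(starts[classes == cls])
    cur_s <- s[1]; cur_e <- s[1] + window - 1L
    for (x in s[-1]) {
      if (x <= cur_e) cur_e <- x + window - 1L else {
        out <- rbind(out, data.frame(start = cur_s, end = cur_e, class = cls))
        cur_s <- x; cur_e <- x + window - 1L
      }
    }
    out <- rbind(out, data.frame(start = cur_s, end = cur_e, class = cls))
  }
  out[order(out$start, out$class), , drop = FALSE]
}

count_basic <- function(s) {
  sum(strsplit(s, "")[[1]] %in% c("K", "R"))
}

count_phi <- function(s) {
  sum(strsplit(s, "")[[1]] %in% c("L", "I", "V", "F", "M"))
}

# Naive two-pass Pearson correlation.
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

random_protein <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V"),
               n, replace = TRUE), collapse = "")
}

# Half-time of a double-exponential recovery by bisection.
oracle_double_thalf <- function(A1, k1, A2, k2) {
  plateau <- A1 + A2
  f <- function(t) A1 * (1 - exp(-k1 * t)) + A2 * (1 - exp(-k2 * t)) - plateau / 2
  stats::uniroot(f, c(1e-9, 1e6), tol = 1e-12)$root
}

scaffold_path <- function() {
  system.file("extdata", "sans_synthetic_scaffold.fasta", package = "nucshuttle")
}

gene_list_path <- function() {
  system.file("extdata", "interactome_genes_example.txt", package = "nucshuttle")
}

motif_table_path <- function() {
  system.file("extdata", "sans_motifs.csv", package = "nucshuttle")
}
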