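motif_table <- utils::read.csv(motif_table_path(), stringsAsFactors = FALSE)

test_that("CRM1 classifier reproduces the curated wild-type classes", {
  nes <- motif_table[motif_table$kind == "NES", ]
  expect_identical(vapply(nes$sequence, classify_crm1_window, character(1),
                          USE.NAMES = FALSE),
                   nes$crm1_class)
})

test_that("CRM1 classifier rejects the curated terminal-leucine mutants", {
  muts <- motif_table$mutant_sequence[motif_table$kind == "NES" &
                                        nzchar(motif_table$mutant_sequence)]
  expect_length(muts, 2L)
  for (m in muts) expect_identical(classify_crm1_window(m), "none")
})

test_that("class precedence and the Ala rule match the regex oracle", {
  # Ala tolerated only in the first hydrophobic slot
  expect_identical(classify_crm1_window("AGGGLGGLGLGGGGG"), "1a")
  expect_identical(classify_crm1_window("LGGGAGGLGLGGGGG"), "none")
  # window matching both 1a and 2 is labelled 1a
  both <- "LGLGLGGLGLGGGGG"
  expect_identical(oracle_crm1_class(both), "1a")
  expect_identical(classify_crm1_window(both), "1a")
})

test_that("NLS scanning flags exactly the basic-rich windows", {
  seq <- protein_sequence("demo", "MKTKMQKKLERRKSSS")
  hits <- scan_nls(seq)
  expect_equal(nrow(hits), 1L)
  expect_gte(count_basic(hits$window), 7L)
  expect_equal(hits$score, count_basic(hits$window) / 12, tolerance = 1e-12)
  none <- scan_nls(protein_sequence("flat", strrep("STGQNP", 10)))
  expect_equal(nrow(none), 0L)
})

test_that("curated NLS windows score by direct basic-residue count", {
  # direct count for RKKILGAVRRRR is 7 of 12 (threshold met, not exceeded)
  expect_identical(count_basic("RKKILGAVRRRR"), 7L)
  expect_identical(count_basic("KTKMQKKLERRK"), 7L)
  for (w in motif_table$sequence[motif_table$kind == "NLS"]) {
    h <- scan_nls(protein_sequence("w", w))
    expect_equal(nrow(h), 1L)
    expect_equal(h$score, 7 / 12, tolerance = 1e-12)
  }
})

test_that("scaffold scan recovers the curated motif coordinates", {
  sc <- read_protein_fasta(scaffold_path())[[1]]
  nls <- scan_nls(sc)
  expect_identical(nls$start, c(213L, 436L))
  expect_identical(nls$end, c(224L, 447L))
  nes <- scan_nes(sc)
  expect_identical(nes$crm1_class, c("1a", "1b", "2"))
  tab <- motif_table[motif_table$kind == "NES", ]
  # each curated window is contained in the matching merged hit
  expect_true(all(nes$start <= tab$start & nes$end >= tab$end))
  # merged-span score is the density of core hydrophobics
  expect_equal(nes$score,
               vapply(nes$window, count_phi, integer(1), USE.NAMES = FALSE) /
                 nchar(nes$window),
               tolerance = 1e-12)
})

test_that("scan_nes agrees with the brute-force window oracle", {
  for (seed in 1:10) {
    res <- random_protein(200L, seed)
    seq <- protein_sequence(paste0("rnd", seed), res)
    got <- scan_nes(seq)
    want <- oracle_nes_hits(res)
    expect_equal(nrow(got), nrow(want), info = paste("seed", seed))
    if (nrow(want)) {
      got <- got[order(got$start, got$crm1_class), ]
      expect_identical(got$start, want$start)
      expect_identical(got$end, want$end)
      expect_identical(got$crm1_class, want$class)
    }
  }
})

test_that("scan_nls hits cover exactly the high-scoring windows", {
  n_flagged <- 0L
  for (seed in 1:10) {
    # splice a basic-rich stretch into a random background so every
    # replicate exercises both flagged and unflagged windows
    res <- random_protein(150L, seed * 31L)
    ins <- random_protein(10L, seed * 31L + 1L)
    ins <- chartr("ACDEFGHIKLMNPQSTVWY", "RKRKRKRKRKRKRKRKRKR", ins)
    res <- paste0(substr(res, 1, 70), ins, substr(res, 81, 150))
    seq <- protein_sequence(paste0("rnd", seed), res)
    hits <- scan_nls(seq)
    flagged <- logical(150L - 11L)
    for (i in seq_along(flagged))
      flagged[i] <- count_basic(substr(res, i, i + 11L)) >= 7L
    n_flagged <- n_flagged + sum(flagged)
    # expected hits: the max-count (leftmost on ties) window of each maximal
    # run of overlapping flagged windows
    starts <- which(flagged)
    want <- integer()
    while (length(starts)) {
      run <- starts[1]
      while (length(starts) > 1 && starts[2] - run[length(run)] < 12L) {
        run <- c(run, starts[2]); starts <- starts[-1]
      }
      starts <- starts[-1]
      cnt <- vapply(run, function(i) count_basic(substr(res, i, i + 11L)),
                    integer(1))
      want <- c(want, run[which.max(cnt)])
    }
    expect_identical(hits$start, want)
  }
  expect_gt(n_flagged, 0L)
})

test_that("variant parsing recognizes the three supported kinds", {
  mis <- parse_variant("K213E")
  expect_identical(mis[c("kind", "ref", "alt")],
                   list(kind = "missense", ref = "K", alt = "E"))
  expect_identical(mis$position, 213L)
  non <- parse_variant("S243*")
  expect_identical(non$kind, "nonsense")
  fs <- parse_variant("S278Pfs*71")
  expect_identical(fs$kind, "frameshift")
  expect_error(parse_variant("not-a-variant"), "parse")
})

test_that("variant application edits, truncates and checks the reference", {
  sc <- read_protein_fasta(scaffold_path())[[1]]
  mut <- apply_variant(sc, parse_variant("K213E"))
  expect_identical(substr(mut$residues, 213, 224), "ETKMQKKLERRK")
  expect_identical(nchar(mut$residues), nchar(sc$residues))
  stopv <- apply_variant(sc, parse_variant("L195*"))
  expect_identical(nchar(stopv$residues), 194L)
  expect_error(apply_variant(sc, parse_variant("R213E")),
               "expected R, found K")
})

test_that("motif diffing reports lost and retained hits after mutation", {
  sc <- read_protein_fasta(scaffold_path())[[1]]
  mut <- apply_variant(sc, parse_variant("K213E"))
  d <- diff_motifs(scan_nls(sc), scan_nls(mut))
  expect_identical(d$lost$start, 213L)
  expect_identical(d$retained$start, 436L)
  expect_equal(nrow(d$gained), 0L)
  dn <- diff_motifs(scan_nes(sc),
                    scan_nes(apply_variant(sc, parse_variant("L195E"))))
  expect_true(any(dn$lost$crm1_class == "1a"))
})

test_that("conservation annotation distinguishes substitution classes", {
  ann <- annotate_conservation("KTKMQKKLERRK", "RTKMQKKLERRK")
  expect_identical(ann$categories[1], "conservative_basic")
  expect_true(all(ann$categories[-1] == "identical"))
  ann2 <- annotate_conservation("KTKMQKKLERRK", "ETKMQKKLERRK")
  expect_identical(ann2$categories[1], "charge_change")
  expect_equal(ann$percent_identity, 100 * 11 / 12, tolerance = 1e-9)
  expect_error(annotate_conservation("KTK", "KTKM"), "equal length")
})

test_that("sequence construction validates the alphabet and start offset", {
  expect_error(protein_sequence("bad", "KTB1"), "alphabet|residue")
  offs <- protein_sequence("frag", "KTKMQKKLERRK", start = 213L)
  h <- scan_nls(offs)
  expect_identical(h$start, 213L)
})
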