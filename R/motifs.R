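AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
PHI <- c("L", "I", "V", "F", "M")   # hydrophobic consensus alphabet
BASIC <- c("K", "R")

#' Construct a protein sequence
#'
#' @param id sequence identifier.
#' @param residues one-letter amino-acid string (20 standard residues plus X).
#' @param start numbering of the first residue (1-based); lets motif windows
#'   excised from a larger protein keep their original coordinates.
#' @return An object of class `protein_sequence`.
#' @export
protein_sequence <- function(id, residues, start = 1L) {
  residues <- toupper(gsub("\\s", "", residues))
  chars <- strsplit(residues, "")[[1]]
  if (length(chars) < 1L) stopf("sequence must have length >= 1")
  bad <- setdiff(unique(chars), c(AA_STANDARD, "X"))
  if (length(bad))
    stopf("non-standard residues in '%s': %s", id, paste(bad, collapse = ", "))
  structure(list(id = id, residues = residues, start = as.integer(start)),
            class = "protein_sequence")
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return A named list of `protein_sequence` objects.
#' @export
read_protein_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  out <- lapply(seq_along(set), function(i)
    protein_sequence(names(set)[i], as.character(set[[i]])))
  names(out) <- vapply(out, `[[`, character(1), "id")
  out
}

seq_chars <- function(seq) strsplit(seq$residues, "")[[1]]

new_motif_hits <- function(df) {
  if (is.null(df)) df <- data.frame(kind = character(), start = integer(),
                                    end = integer(), window = character(),
                                    score = numeric(), crm1_class = character())
  class(df) <- c("motif_hits", "data.frame")
  df
}

#' Scan a protein sequence for basic-residue NLS candidates
#'
#' A transparent sliding-window scanner: each window of `window` residues is
#' scored by its fraction of basic residues (K, R); windows at or above
#' `min_basic_fraction` are candidate nuclear localization signals.
#' Overlapping candidate windows are merged to the maximal-scoring window
#' (leftmost on ties). Scores are a simple basic-residue density in `[0, 1]`
#' and are not comparable to scores of HMM-based NLS predictors.
#'
#' @param seq a [protein_sequence()].
#' @param window window length in residues.
#' @param min_basic_fraction score threshold.
#' @return A `motif_hits` data frame (columns `kind`, `start`, `end`,
#'   `window`, `score`, `crm1_class`) with 1-based inclusive coordinates in
#'   the sequence's own numbering.
#' @export
scan_nls <- function(seq, window = 12L, min_basic_fraction = 7 / 12) {
  stopifnot(inherits(seq, "protein_sequence"))
  ch <- seq_chars(seq)
  n <- length(ch)
  if (window > n) stopf("window longer than the sequence")
  basics <- as.integer(ch %in% BASIC)
  cs <- c(0L, cumsum(basics))
  starts <- seq_len(n - window + 1L)
  score <- (cs[starts + window] - cs[starts]) / window
  cand <- which(score >= min_basic_fraction)
  if (length(cand) == 0L) return(new_motif_hits(NULL))
  # merge runs of overlapping candidate windows, keep the max-scoring window
  grp <- cumsum(c(1L, diff(cand) >= window))
  rows <- lapply(split(cand, grp), function(idx) {
    best <- idx[which.max(score[idx])]
    data.frame(kind = "NLS", start = best, end = best + window - 1L,
               window = paste(ch[best:(best + window - 1L)], collapse = ""),
               score = score[best], crm1_class = NA_character_)
  })
  df <- do.call(rbind, rows)
  df$start <- df$start + seq$start - 1L
  df$end <- df$end + seq$start - 1L
  rownames(df) <- NULL
  new_motif_hits(df)
}

# CRM1 consensus spacings: offsets of the four hydrophobic anchor positions
# relative to the first one.
CRM1_PATTERNS <- list(
  "1a" = c(0L, 4L, 7L, 9L),   # phi-x3-phi-x2-phi-x-phi
  "1b" = c(0L, 3L, 6L, 8L),   # phi-x2-phi-x2-phi-x-phi
  "2"  = c(0L, 2L, 5L, 7L),   # phi-x-phi-x2-phi-x-phi
  "3"  = c(0L, 3L, 7L, 9L)    # phi-x2-phi-x3-phi-x-phi
)

#' Classify a window against the CRM1 leucine-rich NES consensus classes
#'
#' Tests the hydrophobic-anchor spacings of the CRM1 consensus classes
#' (1a: \eqn{\Phi}-X3-\eqn{\Phi}-X2-\eqn{\Phi}-X-\eqn{\Phi}; 1b:
#' \eqn{\Phi}-X2-\eqn{\Phi}-X2-\eqn{\Phi}-X-\eqn{\Phi}; 2:
#' \eqn{\Phi}-X-\eqn{\Phi}-X2-\eqn{\Phi}-X-\eqn{\Phi}; 3:
#' \eqn{\Phi}-X2-\eqn{\Phi}-X3-\eqn{\Phi}-X-\eqn{\Phi}) anywhere inside the
#' window, with \eqn{\Phi = \{L, I, V, F, M\}} and alanine additionally
#' permitted at the first anchor position only. Classes are tested in the
#' precedence order 1a > 1b > 2 > 3 and the first match is returned.
#'
#' @param window residue string of length >= 8.
#' @return `"1a"`, `"1b"`, `"2"`, `"3"`, or `"none"`.
#' @export
classify_crm1_window <- function(window) {
  ch <- strsplit(toupper(window), "")[[1]]
  if (length(ch) < 8L) stopf("window must have at least 8 residues")
  bad <- setdiff(unique(ch), AA_STANDARD)
  if (length(bad))
    stopf("non-standard residues: %s", paste(bad, collapse = ", "))
  is_phi <- ch %in% PHI
  n <- length(ch)
  for (cls in names(CRM1_PATTERNS)) {
    off <- CRM1_PATTERNS[[cls]]
    span <- max(off) + 1L
    if (span > n) next
    for (i in seq_len(n - span + 1L)) {
      pos <- i + off
      phi1_ok <- is_phi[pos[1]] || ch[pos[1]] == "A"
      if (phi1_ok && all(is_phi[pos[-1]])) return(cls)
    }
  }
  "none"
}

#' Scan a protein sequence for CRM1-class NES candidates
#'
#' Slides a window over the sequence and classifies every window with
#' [classify_crm1_window()]; windows with a class other than `"none"` are
#' hits, and overlapping hits of the same class are merged into one span.
#' The score is the hydrophobic-residue (L, I, V, F, M) density of the merged
#' span, a transparent stand-in not comparable to trained NES predictors.
#'
#' @param seq a [protein_sequence()].
#' @param window window length in residues.
#' @return A `motif_hits` data frame with `kind = "NES"` and the CRM1 class of
#'   each merged hit.
#' @export
scan_nes <- function(seq, window = 15L) {
  stopifnot(inherits(seq, "protein_sequence"))
  ch <- seq_chars(seq)
  n <- length(ch)
  if (window > n) stopf("window longer than the sequence")
  starts <- seq_len(n - window + 1L)
  cls <- vapply(starts, function(i)
    classify_crm1_window(paste(ch[i:(i + window - 1L)], collapse = "")),
    character(1))
  hit <- which(cls != "none")
  if (length(hit) == 0L) return(new_motif_hits(NULL))
  rows <- list()
  flush <- function(a, b, cl) {
    w <- paste(ch[a:b], collapse = "")
    data.frame(kind = "NES", start = a, end = b, window = w,
               score = mean(ch[a:b] %in% PHI), crm1_class = cl)
  }
  # merge overlapping windows class by class, so interleaved windows of
  # another class cannot split a run
  for (cl in unique(cls[hit])) {
    s <- hit[cls[hit] == cl]
    grp_start <- s[1]; prev <- s[1]
    for (i in s[-1]) {
      if (i - prev < window) {
        prev <- i
      } else {
        rows[[length(rows) + 1L]] <- flush(grp_start, prev + window - 1L, cl)
        grp_start <- i; prev <- i
      }
    }
    rows[[length(rows) + 1L]] <- flush(grp_start, prev + window - 1L, cl)
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$start, df$crm1_class), , drop = FALSE]
  df$start <- df$start + seq$start - 1L
  df$end <- df$end + seq$start - 1L
  rownames(df) <- NULL
  new_motif_hits(df)
}

#' Parse a variant string
#'
#' Accepted forms: missense `"K213E"`, nonsense `"S243*"`, and frameshift
#' `"S278Pfs*71"` optionally followed by `":<tail>"` giving the novel residues
#' appended after the truncation (e.g. `"S278Pfs*71:PGRT"`).
#'
#' @param x variant string.
#' @return An object of class `variant_spec` with fields `kind`, `position`,
#'   `ref`, `alt` (missense), and `tail` (frameshift, may be `NA`).
#' @export
parse_variant <- function(x) {
  x <- trimws(x)
  m <- regmatches(x, regexec("^([A-Z])([0-9]+)([A-Z])fs\\*([0-9]+)(?::([A-Z]+))?$", x, perl = TRUE))[[1]]
  if (length(m)) {
    return(structure(list(kind = "frameshift", position = as.integer(m[3]),
                          ref = m[2], alt = m[4],
                          tail = if (nzchar(m[6])) m[6] else NA_character_),
                     class = "variant_spec"))
  }
  m <- regmatches(x, regexec("^([A-Z])([0-9]+)\\*$", x))[[1]]
  if (length(m)) {
    return(structure(list(kind = "nonsense", position = as.integer(m[3]),
                          ref = m[2], alt = NA_character_, tail = NA_character_),
                     class = "variant_spec"))
  }
  m <- regmatches(x, regexec("^([A-Z])([0-9]+)([A-Z])$", x))[[1]]
  if (length(m)) {
    if (m[2] == m[4]) stopf("missense variant '%s' does not change the residue", x)
    return(structure(list(kind = "missense", position = as.integer(m[3]),
                          ref = m[2], alt = m[4], tail = NA_character_),
                     class = "variant_spec"))
  }
  stopf("cannot parse variant '%s'", x)
}

#' Apply a sequence variant
#'
#' Missense variants substitute one residue; nonsense variants truncate the
#' sequence so that it ends at `position - 1`; frameshift variants truncate at
#' `position - 1` and append the user-supplied novel tail (a frameshift with
#' no tail degrades to a truncation, with a warning). The reference residue at
#' the variant position must match the sequence.
#'
#' @param seq a [protein_sequence()].
#' @param variant a `variant_spec` or a variant string accepted by
#'   [parse_variant()].
#' @return The mutated `protein_sequence`.
#' @export
apply_variant <- function(seq, variant) {
  stopifnot(inherits(seq, "protein_sequence"))
  if (is.character(variant)) variant <- parse_variant(variant)
  stopifnot(inherits(variant, "variant_spec"))
  ch <- seq_chars(seq)
  idx <- variant$position - seq$start + 1L
  if (idx < 1L || idx > length(ch))
    stopf("position %d outside sequence %s (%d-%d)", variant$position,
          seq$id, seq$start, seq$start + length(ch) - 1L)
  if (ch[idx] != variant$ref)
    stopf("reference mismatch at %d: expected %s, found %s",
          variant$position, variant$ref, ch[idx])
  lab <- sprintf("%s_%s%d%s", seq$id, variant$ref, variant$position,
                 switch(variant$kind, missense = variant$alt, nonsense = "*",
                        frameshift = paste0(variant$alt, "fs")))
  if (variant$kind == "missense") {
    ch[idx] <- variant$alt
    return(protein_sequence(lab, paste(ch, collapse = ""), start = seq$start))
  }
  kept <- if (idx > 1L) ch[seq_len(idx - 1L)] else character(0)
  if (variant$kind == "frameshift") {
    if (is.na(variant$tail)) {
      warnf("frameshift without a novel tail: applying truncation only")
    } else {
      kept <- c(kept, strsplit(variant$tail, "")[[1]])
    }
  }
  if (length(kept) == 0L) stopf("variant removes the entire sequence")
  protein_sequence(lab, paste(kept, collapse = ""), start = seq$start)
}

# TRUE where spans [s1, e1] and [s2, e2] overlap
spans_overlap <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1

#' Diff motif content between a wild-type and a mutant scan
#'
#' Hits are matched by kind (and CRM1 class for NES hits) and overlapping
#' span. Wild-type hits with no mutant match are reported lost; mutant hits
#' with no wild-type match are reported gained (newly emerged motifs are of
#' particular interest when engineering export-dead variants).
#'
#' @param wt_hits,mut_hits `motif_hits` data frames from the same scanner
#'   settings.
#' @return A list of class `motif_diff` with `lost`, `gained` and `retained`
#'   `motif_hits` tables.
#' @export
diff_motifs <- function(wt_hits, mut_hits) {
  match_one <- function(h, other) {
    if (nrow(other) == 0L) return(FALSE)
    same_kind <- other$kind == h$kind
    if (h$kind == "NES")
      same_kind <- same_kind & (other$crm1_class == h$crm1_class)
    any(same_kind & spans_overlap(h$start, h$end, other$start, other$end))
  }
  wt_matched <- vapply(seq_len(nrow(wt_hits)), function(i)
    match_one(wt_hits[i, ], mut_hits), logical(1))
  mut_matched <- vapply(seq_len(nrow(mut_hits)), function(i)
    match_one(mut_hits[i, ], wt_hits), logical(1))
  structure(list(lost = new_motif_hits(wt_hits[!wt_matched, , drop = FALSE]),
                 gained = new_motif_hits(mut_hits[!mut_matched, , drop = FALSE]),
                 retained = new_motif_hits(wt_hits[wt_matched, , drop = FALSE])),
            class = "motif_diff")
}

aa_charge <- function(ch) {
  ifelse(ch %in% c("K", "R", "H"), 1L, ifelse(ch %in% c("D", "E"), -1L, 0L))
}

#' Annotate conservation between two equal-length motif windows
#'
#' Each aligned position is categorized as `identical`, `conservative_basic`
#' (a lysine/arginine exchange, which preserves the positive charge importins
#' recognize), `charge_change` (the net charge differs), or `other`.
#'
#' @param motif_a,motif_b residue strings of equal length (ungapped).
#' @return A list of class `conservation_annotation` with `categories` (one
#'   per position) and `percent_identity`.
#' @export
annotate_conservation <- function(motif_a, motif_b) {
  if (!is.character(motif_a) || length(motif_a) != 1L ||
      !is.character(motif_b) || length(motif_b) != 1L)
    stopf("motif windows must be single residue strings")
  a <- strsplit(toupper(motif_a), "")[[1]]
  b <- strsplit(toupper(motif_b), "")[[1]]
  if (length(a) != length(b)) stopf("motif windows must have equal length")
  cat <- character(length(a))
  for (i in seq_along(a)) {
    cat[i] <- if (a[i] == b[i]) "identical"
    else if (a[i] %in% BASIC && b[i] %in% BASIC) "conservative_basic"
    else if (aa_charge(a[i]) != aa_charge(b[i])) "charge_change"
    else "other"
  }
  structure(list(categories = cat,
                 percent_identity = 100 * mean(cat == "identical")),
            class = "conservation_annotation")
}
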