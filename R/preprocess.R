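# Preprocessing of per-barcode splicing-outcome counts into the
# model-ready dataset: barcode resolution, replicate merging, retention
# filters, PSI, window assembly, wobble indicators and the train/test
# split. Coordinates are 1-based in R; the variable exon occupies
# positions 11..80 of the 90-nt window.

count_cols <- function(df) {
  cols <- grep("^n_", names(df), value = TRUE)
  if (length(cols) == 0L) abort("no count columns (expected names like n_inclusion)")
  cols
}

#' Resolve barcode-to-exon assignments
#'
#' A barcode maps to an exon iff, after discarding exon sequences observed
#' only once under that barcode (likely sequencing errors), exactly one
#' exon remains, and the barcode has at least two DNA reads in total.
#'
#' @param pairs Tibble with columns `barcode`, `exon_seq`, `dna_reads`.
#' @return Tibble `barcode`, `exon_seq`, `dna_reads` (one row per retained
#'   barcode; `dna_reads` is the barcode total).
#' @export
resolve_barcode_map <- function(pairs) {
  pairs <- as_tibble(pairs)
  stopifnot(all(c("barcode", "exon_seq", "dna_reads") %in% names(pairs)))
  pairs |>
    group_by(.data$barcode, .data$exon_seq) |>
    summarise(dna_reads = sum(.data$dna_reads), .groups = "drop") |>
    group_by(.data$barcode) |>
    summarise(
      total_reads = sum(.data$dna_reads),
      n_exons_kept = sum(.data$dna_reads >= 2L),
      exon_seq = if (sum(.data$dna_reads >= 2L) == 1L)
        .data$exon_seq[.data$dna_reads >= 2L][1] else NA_character_,
      .groups = "drop") |>
    filter(.data$n_exons_kept == 1L, .data$total_reads >= 2L) |>
    select("barcode", "exon_seq", dna_reads = "total_reads")
}

#' Merge replicate count tables
#'
#' Sums every `n_*` count column per barcode (and exon) across replicates.
#' Barcodes missing from a replicate count as zero.
#'
#' @param records Tibble of per-replicate records with columns
#'   `barcode`, optionally `exon_seq` and `replicate`, and `n_*` counts.
#' @return Tibble with one row per barcode and summed counts.
#' @export
merge_replicates <- function(records) {
  records <- as_tibble(records)
  cols <- count_cols(records)
  if (any(vapply(records[cols], function(x) any(x < 0), logical(1)))) {
    abort("negative counts are invalid")
  }
  keys <- intersect(c("barcode", "exon_seq"), names(records))
  records |>
    group_by(across(dplyr::all_of(keys))) |>
    summarise(across(dplyr::all_of(cols), sum), .groups = "drop")
}

has_site <- function(seq_rna, site_rna, site_rc_rna) {
  grepl(site_rna, seq_rna, fixed = TRUE) | grepl(site_rc_rna, seq_rna, fixed = TRUE)
}

#' Retention filter for merged barcodes
#'
#' Keeps barcodes with (1) at least `min_total_reads` reads over all
#' outcome categories, (2) no occurrence of the restriction `site` or its
#' reverse complement in the exon or the barcode, and (3) inclusion plus
#' skipping reads making up at least `min_incl_skip_fraction` of all reads.
#'
#' @param records Merged count tibble (columns `barcode`, `exon_seq`,
#'   `n_inclusion`, `n_skipping`, further `n_*` columns counted in the
#'   total).
#' @param min_total_reads Minimum total reads (default 60).
#' @param site Recognition sequence screened on both strands (default the
#'   Esp3I/BsmBI site `CGTCTC`).
#' @param min_incl_skip_fraction Minimum informative-read fraction
#'   (default 0.8).
#' @return Filtered tibble, same columns.
#' @export
filter_barcodes <- function(records, min_total_reads = 60, site = "CGTCTC",
                            min_incl_skip_fraction = 0.8) {
  records <- as_tibble(records)
  cols <- count_cols(records)
  site_rna <- rna_normalize(site)
  site_rc <- reverse_complement(site_rna)
  total <- Reduce(`+`, records[cols])
  informative <- records$n_inclusion + records$n_skipping
  exon_rna <- rna_normalize(records$exon_seq)
  # barcodes are screened for the site but not alphabet-validated
  bc_rna <- toupper(chartr("tT", "uU", records$barcode))
  keep <- total >= min_total_reads &
    !has_site(exon_rna, site_rna, site_rc) &
    !has_site(bc_rna, site_rna, site_rc) &
    informative / total >= min_incl_skip_fraction
  records[keep, , drop = FALSE]
}

#' Percent spliced in
#'
#' `n_inclusion / (n_inclusion + n_skipping)`.
#'
#' @param n_inclusion,n_skipping Non-negative integer vectors.
#' @return PSI in `[0, 1]`.
#' @export
compute_psi <- function(n_inclusion, n_skipping) {
  if (any(n_inclusion < 0) || any(n_skipping < 0)) abort("counts must be >= 0")
  denom <- n_inclusion + n_skipping
  if (any(denom == 0)) abort("PSI undefined: zero inclusion + skipping reads")
  n_inclusion / denom
}

#' G-U wobble indicator vector
#'
#' Builds the pair table of `structure` and flags both positions of every
#' base pair whose bases are G and U.
#'
#' @param sequence RNA (or DNA) string.
#' @param structure Balanced dot-bracket string, same length.
#' @return Integer 0/1 vector along the sequence.
#' @export
wobble_vector <- function(sequence, structure) {
  sequence <- rna_normalize(sequence)
  if (nchar(sequence) != nchar(structure)) {
    abort("sequence and structure lengths differ")
  }
  partner <- pair_table(structure)
  chars <- strsplit(sequence, "")[[1]]
  out <- integer(length(chars))
  paired <- which(!is.na(partner))
  for (i in paired) {
    pr <- sort(c(chars[i], chars[partner[i]]))
    if (pr[1] == "G" && pr[2] == "U") out[i] <- 1L
  }
  out
}

#' Random train/test partition
#'
#' Disjoint, exhaustive split with `round(train_fraction * n)` training
#' rows (half-away-from-zero rounding), deterministic given `seed`.
#'
#' @param records A tibble.
#' @param train_fraction Fraction assigned to training (default 0.8).
#' @param seed Integer seed.
#' @return The input with an added `split` column (`"train"` / `"test"`).
#' @export
split_train_test <- function(records, train_fraction = 0.8, seed = 1) {
  records <- as_tibble(records)
  n <- nrow(records)
  n_train <- round_half_up(train_fraction * n)
  set.seed(seed)
  idx <- sample.int(n, n_train)
  records$split <- "test"
  records$split[idx] <- "train"
  records
}

#' Assemble the model-ready dataset from counts and structures
#'
#' Runs the full preprocessing chain: merge replicates, apply the
#' retention filters, compute PSI, embed each exon in the 90-nt window
#' between the fixed flanks, attach structures (supplied, or folded with
#' the toy folder), compute wobble indicators, and split train/test.
#'
#' @param records Per-barcode count tibble (possibly several replicates).
#' @param structures Optional tibble `barcode`, `structure` with
#'   dot-bracket strings for the 90-nt windows. If `NULL`, windows are
#'   folded with [fold_toy()] (synthetic-data path).
#' @param min_total_reads,site,min_incl_skip_fraction See [filter_barcodes()].
#' @param train_fraction,seed See [split_train_test()].
#' @param flanks Named vector `flank5`/`flank3`; default [splice_flanks()].
#' @return Tibble of dataset records: `barcode`, `sequence`, `structure`,
#'   `wobble`, `n_inclusion`, `n_skipping`, `psi`, `split`.
#' @export
preprocess_assay <- function(records, structures = NULL,
                             min_total_reads = 60, site = "CGTCTC",
                             min_incl_skip_fraction = 0.8,
                             train_fraction = 0.8, seed = 1,
                             flanks = splice_flanks()) {
  merged <- merge_replicates(records)
  kept <- filter_barcodes(merged, min_total_reads = min_total_reads,
                          site = site,
                          min_incl_skip_fraction = min_incl_skip_fraction)
  kept$psi <- compute_psi(kept$n_inclusion, kept$n_skipping)
  kept$sequence <- paste0(flanks[["flank5"]], rna_normalize(kept$exon_seq),
                          flanks[["flank3"]])
  if (is.null(structures)) {
    kept$structure <- fold_toy(kept$sequence)
  } else {
    structures <- as_tibble(structures)
    kept <- left_join(kept, structures[c("barcode", "structure")], by = "barcode")
    if (anyNA(kept$structure)) {
      abort("missing structure for one or more retained barcodes")
    }
  }
  kept$wobble <- vapply(seq_len(nrow(kept)), function(i) {
    paste(wobble_vector(kept$sequence[i], kept$structure[i]), collapse = "")
  }, character(1))
  kept <- split_train_test(kept, train_fraction = train_fraction, seed = seed)
  kept |>
    select("barcode", "sequence", "structure", "wobble",
           "n_inclusion", "n_skipping", "psi", "split")
}
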