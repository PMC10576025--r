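# Readers and writers: FASTA, Vienna-style dot-bracket files, TSV count
# tables and datasets, and the JSON model container.

tool_version_comment <- function() {
  sprintf("# splicebalance %s",
          as.character(utils::packageVersion("splicebalance")))
}

#' Read a FASTA file
#'
#' Order-preserving; sequences are uppercased and normalized T -> U.
#'
#' @param path FASTA file path.
#' @return Tibble with `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (file.size(path) == 0L) {
    return(tibble(id = character(0), sequence = character(0)))
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) abort("duplicate FASTA ids")
  tibble(id = ids,
         sequence = unname(rna_normalize(as.character(set), allow_n = TRUE)))
}

#' Write a FASTA file
#'
#' @param x Tibble with `id` and `sequence`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(x, path, width = 60) {
  set <- Biostrings::BStringSet(setNames(x$sequence, x$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

validate_structure <- function(structure, id = NULL, sequence = NULL) {
  ok <- tryCatch({
    pair_table(structure)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    abort(sprintf("unbalanced dot-bracket structure%s",
                  if (is.null(id)) "" else sprintf(" for record '%s'", id)))
  }
  if (!is.null(sequence) && nchar(sequence) != nchar(structure)) {
    abort(sprintf("structure length differs from sequence%s",
                  if (is.null(id)) "" else sprintf(" for record '%s'", id)))
  }
  invisible(TRUE)
}

#' Read secondary structures
#'
#' Accepts Vienna-style triplets (`>id` / sequence / dot-bracket) or a
#' two-column TSV (`id`, `structure`; optional `sequence` column).
#' Structures are validated (balanced brackets, length match when the
#' sequence is present).
#'
#' @param path Input path.
#' @return Tibble with `id`, `structure` (and `sequence` when present).
#' @export
read_structures <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(tibble(id = character(0), structure = character(0)))
  if (startsWith(lines[1], ">")) {
    if (length(lines) %% 3L != 0L) {
      abort("Vienna-style structure file must contain (header, sequence, structure) triplets")
    }
    ids <- sub("^>", "", trimws(lines[seq(1, length(lines), by = 3)]))
    ids <- sub("\\s.*$", "", ids)
    seqs <- rna_normalize(trimws(lines[seq(2, length(lines), by = 3)]))
    structs <- trimws(lines[seq(3, length(lines), by = 3)])
    out <- tibble(id = ids, sequence = seqs, structure = structs)
  } else {
    out <- utils::read.delim(path, header = TRUE, comment.char = "#",
                             stringsAsFactors = FALSE)
    out <- as_tibble(out)
    if (!all(c("id", "structure") %in% names(out))) {
      abort("structure TSV must have columns 'id' and 'structure'")
    }
  }
  has_seq <- "sequence" %in% names(out)
  for (i in seq_len(nrow(out))) {
    validate_structure(out$structure[i], id = out$id[i],
                       sequence = if (has_seq) out$sequence[i] else NULL)
  }
  out
}

write_tsv_commented <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(tool_version_comment(), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a per-barcode count table
#'
#' TSV with a tool-version comment line and a header.
#'
#' @param x Count tibble.
#' @param path File path.
#' @return `read_count_table`: tibble.
#' @export
write_count_table <- function(x, path) write_tsv_commented(x, path)

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  as_tibble(utils::read.delim(path, header = TRUE, comment.char = "#",
                              stringsAsFactors = FALSE))
}

#' @rdname write_count_table
#' @export
write_dataset <- function(x, path) write_tsv_commented(x, path)

#' @rdname write_count_table
#' @export
read_dataset <- function(path) {
  # read everything as character first: wobble indicator strings must not
  # lose their leading zeros to numeric coercion
  out <- as_tibble(utils::read.delim(path, header = TRUE, comment.char = "#",
                                     colClasses = "character",
                                     stringsAsFactors = FALSE))
  keep_chr <- c("barcode", "exon_seq", "sequence", "structure", "wobble",
                "split", "id", "variant", "filter", "scm", "side")
  for (nm in setdiff(names(out), keep_chr)) {
    out[[nm]] <- utils::type.convert(out[[nm]], as.is = TRUE)
  }
  out
}

MODEL_FORMAT <- "splicebalance-model"
MODEL_VERSION <- 1L

#' Save / load a model container
#'
#' Single-file JSON serialization of the full parameter set (kernels,
#' position biases, basal strength, tuner, metadata). The round trip is
#' bit-exact.
#'
#' @param model A `splice_model`.
#' @param path File path.
#' @return `load_model`: the restored `splice_model`.
#' @export
save_model <- function(model, path) {
  scms <- lapply(model$scms, function(s) {
    list(dim = dim(s$alpha), alpha = as.numeric(s$alpha),
         beta_dim = dim(s$beta), beta = as.numeric(s$beta))
  })
  tuner <- model$tuner
  if (tuner$type == "full") tuner$W2 <- as.numeric(tuner$W2)
  payload <- list(format = MODEL_FORMAT, version = MODEL_VERSION,
                  d = model$d, use_struct = model$use_struct,
                  stage = model$stage, B = model$B,
                  channels = model$channels, tuner = tuner, scms = scms)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17))
  writeLines(json, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                      error = function(e) {
                        abort(sprintf("cannot parse model file '%s': %s",
                                      path, conditionMessage(e)))
                      })
  if (is.null(payload$format) || payload$format != MODEL_FORMAT) {
    abort("not a splicebalance model container")
  }
  if (payload$version != MODEL_VERSION) {
    abort(sprintf("model container version %s; this build reads version %s",
                  payload$version, MODEL_VERSION))
  }
  scms <- lapply(payload$scms, function(s) {
    list(alpha = array(as.numeric(s$alpha), dim = s$dim),
         beta = matrix(as.numeric(s$beta), s$beta_dim[1], s$beta_dim[2]))
  })
  tuner <- payload$tuner
  num_fields <- setdiff(names(tuner), "type")
  tuner[num_fields] <- lapply(tuner[num_fields], as.numeric)
  if (tuner$type == "full") {
    h <- length(tuner$W1)
    tuner$W2 <- matrix(tuner$W2, h, h)
  }
  structure(list(scms = scms[SCM_NAMES], B = as.numeric(payload$B), tuner = tuner,
                 d = as.integer(payload$d), use_struct = payload$use_struct,
                 stage = payload$stage, history = NULL,
                 channels = payload$channels),
            class = "splice_model")
}

#' Export a synthetic assay to plain-text files
#'
#' Writes the count table TSV, a FASTA of the 90-nt windows, a
#' Vienna-style structure file and the truth sidecar TSV.
#'
#' @param assay A [build_synthetic_assay()] result.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_synthetic_assay <- function(assay, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(assay$records, file.path(dir, "counts.tsv"))
  write_fasta(tibble(id = assay$truth$barcode, sequence = assay$truth$sequence),
              file.path(dir, "windows.fasta"))
  con <- file(file.path(dir, "structures.vienna"), "w")
  for (i in seq_len(nrow(assay$truth))) {
    writeLines(c(paste0(">", assay$truth$barcode[i]),
                 assay$truth$sequence[i], assay$truth$structure[i]), con)
  }
  close(con)
  write_tsv_commented(assay$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
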