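# Post-bioinformatics filtering of taxonomically assigned MOTU read-count
# tables, down to the binary detection matrix used by the rest of the
# pipeline.  Filter order is fixed: negative-control removal -> similarity
# threshold -> taxonomic-level assignment -> tag-jump filter -> 1/0 coding.

#' Construct a MOTU read-count table
#'
#' @param motus data.frame with one row per MOTU and columns `motu_id`,
#'   `candidates` (`;`-separated candidate taxa from reference-database
#'   matching), `best_similarity` (best match, fraction in \[0, 1\]),
#'   `in_negative_control` (logical), `whitelist` (logical: keep even when
#'   below the similarity threshold, e.g. a *Marmota* MOTU whose only close
#'   relatives in the database are congeners).
#' @param counts non-negative integer matrix, MOTUs x samples, with
#'   `motu_id` rownames and sample colnames.
#' @param library_of_sample named character vector mapping each sample to
#'   its sequencing library.
#' @return an object of class `motu_table`.
#' @export
motu_table <- function(motus, counts, library_of_sample) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- motus$motu_id
  stopifnot(is.data.frame(motus),
            all(c("motu_id", "candidates", "best_similarity",
                  "in_negative_control", "whitelist") %in% names(motus)))
  if (anyDuplicated(motus$motu_id)) stop("duplicated motu_id")
  if (!identical(sort(rownames(counts)), sort(as.character(motus$motu_id))))
    stop("counts rownames do not match motu_id")
  counts <- counts[as.character(motus$motu_id), , drop = FALSE]
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  if (any(motus$best_similarity < 0 | motus$best_similarity > 1))
    stop("best_similarity must lie in [0, 1]")
  if (is.null(colnames(counts))) stop("counts must have sample colnames")
  miss <- setdiff(colnames(counts), names(library_of_sample))
  if (length(miss))
    stop("samples without a library: ", paste(miss, collapse = ", "))
  if (!"assigned_name" %in% names(motus)) motus$assigned_name <- NA_character_
  if (!"assigned_rank" %in% names(motus)) motus$assigned_rank <- NA_character_
  structure(list(motus = motus, counts = counts,
                 library_of_sample = library_of_sample[colnames(counts)]),
            class = "motu_table")
}

#' @export
print.motu_table <- function(x, ...) {
  cat("motu_table:", nrow(x$counts), "MOTUs x", ncol(x$counts), "samples;",
      sum(x$counts), "reads\n")
  invisible(x)
}

.subset_motus <- function(t, keep) {
  t$motus <- t$motus[keep, , drop = FALSE]
  t$counts <- t$counts[keep, , drop = FALSE]
  if (nrow(t$counts) == 0) warning("all MOTUs removed; table is empty")
  t
}

#' Remove MOTUs found in negative controls
#'
#' Any MOTU flagged as present in an extraction or PCR negative control is
#' deleted outright.
#'
#' @param t a [motu_table()].
#' @return the filtered `motu_table`.
#' @export
remove_control_motus <- function(t) {
  stopifnot(inherits(t, "motu_table"))
  .subset_motus(t, !t$motus$in_negative_control)
}

#' Remove MOTUs below the reference-database similarity threshold
#'
#' MOTUs whose best match to the reference database falls strictly below
#' `threshold` are removed, unless whitelisted (used for taxa whose only
#' database relatives are congeners, so a lower similarity is expected).
#' A similarity exactly at the threshold is retained.
#'
#' @param t a [motu_table()].
#' @param threshold similarity fraction in (0, 1]; default 0.96.
#' @return the filtered `motu_table`.
#' @export
filter_similarity <- function(t, threshold = 0.96) {
  stopifnot(inherits(t, "motu_table"), threshold > 0, threshold <= 1)
  keep <- t$motus$best_similarity >= threshold | t$motus$whitelist
  .subset_motus(t, keep)
}

#' Genus -> subfamily lookup used for ambiguous assignments
#'
#' Minimal built-in map covering the arvicoline rodents; extend via the
#' `subfamily_map` argument of [assign_reporting_level()].
#' @return named character vector (genus -> subfamily).
#' @export
default_subfamily_map <- function() {
  c(Myodes = "Arvicolinae", Microtus = "Arvicolinae",
    Ondatra = "Arvicolinae", Phenacomys = "Arvicolinae",
    Lemmus = "Arvicolinae", Clethrionomys = "Arvicolinae")
}

.genus_of <- function(x) vapply(strsplit(trimws(x), "\\s+"),
                                function(w) w[[1]], "")

#' Assign each MOTU to its reporting taxonomic level
#'
#' A MOTU matching a single candidate taxon is reported at species level;
#' candidates confined to one genus collapse to a genus-level taxon;
#' candidates spanning several genera of one subfamily collapse to the
#' subfamily.  Candidates spanning more than one subfamily (or genera
#' absent from the subfamily map) cannot be assigned and are removed with
#' a warning.
#'
#' @param t a [motu_table()] whose `candidates` column is populated.
#' @param subfamily_map named character vector genus -> subfamily,
#'   merged over [default_subfamily_map()].
#' @return `motu_table` with `assigned_name`/`assigned_rank` filled and
#'   unassignable MOTUs removed.
#' @export
assign_reporting_level <- function(t, subfamily_map = NULL) {
  stopifnot(inherits(t, "motu_table"))
  map <- default_subfamily_map()
  if (!is.null(subfamily_map)) map[names(subfamily_map)] <- subfamily_map
  name <- rank <- rep(NA_character_, nrow(t$motus))
  for (i in seq_len(nrow(t$motus))) {
    cand <- unique(trimws(strsplit(t$motus$candidates[i], ";")[[1]]))
    cand <- cand[nzchar(cand)]
    if (length(cand) == 0) next
    if (length(cand) == 1) {
      name[i] <- cand; rank[i] <- "species"; next
    }
    genera <- unique(.genus_of(cand))
    if (length(genera) == 1) {
      name[i] <- genera; rank[i] <- "genus"; next
    }
    subf <- unique(map[genera])
    if (length(subf) == 1 && !anyNA(subf)) {
      name[i] <- unname(subf); rank[i] <- "subfamily"
    }
  }
  drop <- is.na(name)
  if (any(drop))
    warning("unassignable MOTU(s) removed (candidates span > 1 subfamily ",
            "or no candidates): ",
            paste(t$motus$motu_id[drop], collapse = ", "))
  t$motus$assigned_name <- name
  t$motus$assigned_rank <- rank
  .subset_motus(t, !drop)
}

#' Discard low-frequency occurrences caused by tag jumps
#'
#' Tag jumps assign a small number of reads to the wrong sample of a
#' sequencing library.  For each assigned taxon and each library, a
#' sample's count is zeroed when it is below `freq` times the taxon's
#' total read count in that library.  Totals are computed once from the
#' input table (a single pass, not iterated).
#'
#' @param t a [motu_table()] with assigned taxa (see
#'   [assign_reporting_level()]).
#' @param freq frequency-of-occurrence threshold; default 0.001.
#' @return `motu_table` with sub-threshold cells zeroed.
#' @export
filter_tag_jumps <- function(t, freq = 0.001) {
  stopifnot(inherits(t, "motu_table"), freq >= 0, freq < 1)
  if (anyNA(t$motus$assigned_name))
    stop("taxa must be assigned before tag-jump filtering")
  lib <- t$library_of_sample
  taxon <- t$motus$assigned_name
  counts <- t$counts
  for (lb in unique(lib)) {
    in_lib <- lib == lb
    for (tx in unique(taxon)) {
      rows <- taxon == tx
      tot <- sum(counts[rows, in_lib])
      if (tot == 0) next
      # column totals of the taxon (cells of congeneric MOTUs pool)
      cell <- colSums(counts[rows, in_lib, drop = FALSE])
      kill <- cell / tot < freq
      if (any(kill))
        counts[rows, which(in_lib)[kill]] <- 0L
    }
  }
  t$counts <- counts
  t
}

#' Collapse a filtered MOTU table to a binary detection matrix
#'
#' MOTUs sharing an assigned taxon pool; a taxon is detected in a sample
#' when its pooled post-filter read count is positive.  Per-sample effort
#' is the volume of water filtered (litres), taken from the sample
#' metadata.
#'
#' @param t a filtered, assigned [motu_table()].
#' @param samples a [read_water_samples()] table covering every sample in
#'   `t`.
#' @return a [detection_matrix()].
#' @export
to_detection_matrix <- function(t, samples) {
  stopifnot(inherits(t, "motu_table"))
  if (anyNA(t$motus$assigned_name))
    stop("taxa must be assigned before binarisation")
  miss <- setdiff(colnames(t$counts), samples$sample_id)
  if (length(miss))
    stop("sample(s) absent from metadata: ", paste(miss, collapse = ", "))
  taxa <- sort(unique(t$motus$assigned_name))
  pooled <- rowsum(t$counts, group = t$motus$assigned_name)
  y <- (pooled[taxa, , drop = FALSE] > 0) * 1L
  eff <- samples$volume_l[match(colnames(y), samples$sample_id)]
  names(eff) <- colnames(y)
  detection_matrix(y, eff)
}

#' Run the full MOTU filter chain
#'
#' Fixed order: control-MOTU removal, similarity threshold, reporting-level
#' assignment, tag-jump filter, binarisation.
#'
#' @inheritParams to_detection_matrix
#' @inheritParams filter_similarity
#' @inheritParams filter_tag_jumps
#' @param subfamily_map see [assign_reporting_level()].
#' @return a [detection_matrix()].
#' @export
filter_motus <- function(t, samples, threshold = 0.96, freq = 0.001,
                         subfamily_map = NULL) {
  t <- remove_control_motus(t)
  t <- filter_similarity(t, threshold)
  t <- assign_reporting_level(t, subfamily_map)
  t <- filter_tag_jumps(t, freq)
  to_detection_matrix(t, samples)
}

#' Percentage of sequencing reads retained after filtering
#'
#' @param total total raw reads.
#' @param retained reads remaining after bioinformatic filtering.
#' @return percentage, rounded to one decimal place.
#' @export
read_retention <- function(total, retained) {
  stopifnot(total > 0, retained >= 0, retained <= total)
  round(100 * retained / total, 1)
}

#' Read a MOTU table from disk
#'
#' @param counts_path TSV/CSV with columns `motu_id`, `candidates`,
#'   `best_similarity`, `in_negative_control`, `whitelist`, followed by
#'   one count column per sample.
#' @param libraries_path TSV/CSV with columns `sample_id`, `library`.
#' @return a [motu_table()].
#' @export
read_motu_table <- function(counts_path, libraries_path) {
  d <- .read_table(counts_path)
  meta_cols <- c("motu_id", "candidates", "best_similarity",
                 "in_negative_control", "whitelist")
  miss <- setdiff(meta_cols, names(d))
  if (length(miss))
    stop("missing column(s) in ", counts_path, ": ",
         paste(miss, collapse = ", "))
  samp_cols <- setdiff(names(d),
                       c(meta_cols, "assigned_name", "assigned_rank"))
  counts <- as.matrix(d[samp_cols])
  rownames(counts) <- d$motu_id
  libs <- .read_table(libraries_path)
  if (!all(c("sample_id", "library") %in% names(libs)))
    stop("library table needs columns sample_id, library")
  lib <- stats::setNames(as.character(libs$library), libs$sample_id)
  motu_table(d[meta_cols], counts, lib)
}
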