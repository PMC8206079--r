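# Typed readers/writers and validation for the tabular inputs and outputs
# shared by the pipeline: binary detection matrices with per-unit sampling
# effort, taxon attribute tables, water-sample metadata, camera-trap
# records and survey cost tables.

#' Round half away from zero to the nearest integer
#'
#' Commercial ("half-up") rounding, used for whole-dollar cost reporting.
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

.taxon_groups <- c("bears", "canids", "felids", "ungulates", "lagomorphs",
                   "small_mammals", "bats", "other")
.taxon_diets <- c("carnivore", "omnivore", "herbivore")
.taxon_ranks <- c("species", "genus", "subfamily")

#' Build a validated taxon attribute table
#'
#' Taxa are identified by a binomial or higher-rank label and carry the
#' covariates used throughout the analysis: higher taxonomic group, diet
#' class, body mass, and whether a camera-trap survey can detect and
#' identify them (volant mammals, most small rodents and semi-aquatic
#' species cannot).
#'
#' @param name character, unique taxon labels.
#' @param rank one of `"species"`, `"genus"`, `"subfamily"` (recycled).
#' @param group higher taxonomic group, one of `r paste(.taxon_groups, collapse = ", ")`.
#' @param diet one of `"carnivore"`, `"omnivore"`, `"herbivore"`.
#' @param body_mass average adult body mass in kg, `NA` allowed.
#' @param camera_detectable logical.
#' @return a `data.frame` of class `taxon_table`.
#' @export
taxon_table <- function(name, rank = "species", group = "other", diet = NA,
                        body_mass = NA, camera_detectable = TRUE) {
  name <- as.character(name)
  if (anyDuplicated(name))
    stop("duplicated taxon names: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  d <- data.frame(name = name,
                  rank = rep_len(as.character(rank), length(name)),
                  group = rep_len(as.character(group), length(name)),
                  diet = rep_len(as.character(diet), length(name)),
                  body_mass = rep_len(as.numeric(body_mass), length(name)),
                  camera_detectable = rep_len(as.logical(camera_detectable),
                                              length(name)),
                  stringsAsFactors = FALSE)
  if (!all(d$rank %in% .taxon_ranks))
    stop("rank must be one of: ", paste(.taxon_ranks, collapse = ", "))
  if (!all(d$group %in% .taxon_groups))
    stop("group must be one of: ", paste(.taxon_groups, collapse = ", "))
  ok_diet <- is.na(d$diet) | d$diet %in% .taxon_diets
  if (!all(ok_diet))
    stop("diet must be one of: ", paste(.taxon_diets, collapse = ", "))
  # consistency: felids are obligate carnivores
  bad <- d$group == "felids" & !is.na(d$diet) & d$diet != "carnivore"
  if (any(bad))
    stop("felids must have diet 'carnivore': ",
         paste(d$name[bad], collapse = ", "))
  if (any(!is.na(d$body_mass) & d$body_mass <= 0))
    stop("body_mass must be positive")
  class(d) <- c("taxon_table", "data.frame")
  d
}

#' Construct a binary detection matrix with per-unit sampling effort
#'
#' The central data container: a taxa-by-sampling-unit 0/1 matrix together
#' with a positive effort value per unit (litres of water filtered for
#' eDNA samples, active trap-days for camera sites).  Rows are ordered
#' alphabetically by taxon and columns by unit id so that equal surveys
#' compare identical.
#'
#' @param y 0/1 matrix with taxon rownames and unit colnames.
#' @param effort positive numeric, one value per column of `y`; either
#'   named by unit id or given in column order.
#' @param taxa optional [taxon_table()] carrying attributes for (at least)
#'   the taxa in `y`.
#' @return an object of class `detection_matrix` with elements `y`,
#'   `effort`, `taxa`.
#' @export
detection_matrix <- function(y, effort, taxa = NULL) {
  y <- as.matrix(y)
  if (is.null(rownames(y)) || is.null(colnames(y)))
    stop("`y` must have taxon rownames and unit colnames")
  bad <- which(!(y %in% c(0, 1)))
  if (length(bad))
    stop("detection matrix cells must be 0 or 1; offending cells at ",
         paste(utils::head(paste0("[", row(y)[bad], ",", col(y)[bad], "]"), 5),
               collapse = " "))
  storage.mode(y) <- "integer"
  effort <- as.numeric(effort)
  if (length(effort) != ncol(y))
    stop("need one effort value per sampling unit")
  if (is.null(names(effort))) names(effort) <- colnames(y)
  if (!setequal(names(effort), colnames(y)))
    stop("effort names do not match unit ids")
  if (any(!is.finite(effort) | effort <= 0))
    stop("effort must be finite and positive for every unit")
  ro <- order(rownames(y)); co <- order(colnames(y))
  y <- y[ro, co, drop = FALSE]
  effort <- effort[colnames(y)]
  if (!is.null(taxa)) {
    if (!inherits(taxa, "taxon_table")) taxa <- taxon_table(name = taxa)
    miss <- setdiff(rownames(y), taxa$name)
    if (length(miss))
      stop("taxa missing from taxon table: ", paste(miss, collapse = ", "))
  }
  structure(list(y = y, effort = effort, taxa = taxa),
            class = "detection_matrix")
}

#' @export
print.detection_matrix <- function(x, ...) {
  cat("detection_matrix:", nrow(x$y), "taxa x", ncol(x$y), "units;",
      "effort", paste(range(x$effort), collapse = "-"), "\n")
  invisible(x)
}

#' @export
dim.detection_matrix <- function(x) dim(x$y)

.read_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

.write_table <- function(d, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(d, path, sep = sep, row.names = FALSE, quote = FALSE)
}

#' Read a detection matrix from a long-format table
#'
#' Canonical on-disk layout: one row per (taxon, unit) pair with columns
#' `taxon`, `unit_id`, `detected` plus a per-unit effort column
#' (`effort_column`).  Pairs absent from the file are taken as
#' non-detections.  TSV when the file ends in `.tsv`, otherwise CSV.
#'
#' @param path file path.
#' @param effort_column name of the effort column (litres or trap-days).
#' @return a [detection_matrix()].
#' @export
read_detection_matrix <- function(path, effort_column = "effort") {
  d <- .read_table(path)
  need <- c("taxon", "unit_id", "detected", effort_column)
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  bad <- which(!(d$detected %in% c(0, 1)))
  if (length(bad))
    stop("non-binary `detected` values at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  key <- paste(d$taxon, d$unit_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (taxon, unit) pair(s) at row(s) ",
         paste(utils::head(which(duplicated(key)), 5), collapse = ", "))
  eff_by_unit <- tapply(d[[effort_column]], d$unit_id,
                        function(e) unique(as.numeric(e)))
  n_eff <- vapply(eff_by_unit, length, 1L)
  if (any(n_eff != 1))
    stop("inconsistent effort within unit(s): ",
         paste(names(eff_by_unit)[n_eff != 1], collapse = ", "))
  taxa <- sort(unique(d$taxon)); units <- sort(unique(d$unit_id))
  y <- matrix(0L, length(taxa), length(units), dimnames = list(taxa, units))
  y[cbind(match(d$taxon, taxa), match(d$unit_id, units))] <-
    as.integer(d$detected)
  detection_matrix(y, unlist(eff_by_unit)[units])
}

#' Write a detection matrix in long format
#'
#' @param m a [detection_matrix()].
#' @param path destination path (`.tsv` for TSV, otherwise CSV).
#' @param effort_column name for the effort column.
#' @return `path`, invisibly.
#' @export
write_detection_matrix <- function(m, path, effort_column = "effort") {
  stopifnot(inherits(m, "detection_matrix"))
  d <- data.frame(taxon = rep(rownames(m$y), times = ncol(m$y)),
                  unit_id = rep(colnames(m$y), each = nrow(m$y)),
                  detected = as.integer(m$y),
                  stringsAsFactors = FALSE)
  d[[effort_column]] <- m$effort[d$unit_id]
  .write_table(d, path)
  invisible(path)
}

#' Read water-sample metadata
#'
#' Expects columns `sample_id`, `site_id`, `year`, `design`
#' (`spatial`/`catchment`), `volume_l`, `rain_mm` (rainfall the day before
#' sampling), `catchment_km2` (upstream watershed area).
#'
#' @param path CSV/TSV path.
#' @return a validated `data.frame` of class `water_samples`.
#' @export
read_water_samples <- function(path) {
  d <- .read_table(path)
  need <- c("sample_id", "site_id", "year", "design", "volume_l", "rain_mm",
            "catchment_km2")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  if (anyDuplicated(d$sample_id))
    stop("duplicated sample_id(s): ",
         paste(unique(d$sample_id[duplicated(d$sample_id)]), collapse = ", "))
  if (!all(d$design %in% c("spatial", "catchment")))
    stop("design must be 'spatial' or 'catchment'")
  if (any(!is.finite(d$volume_l) | d$volume_l <= 0))
    stop("volume_l must be finite and positive")
  if (any(d$rain_mm < 0)) stop("rain_mm must be >= 0")
  if (any(d$catchment_km2 <= 0)) stop("catchment_km2 must be positive")
  class(d) <- c("water_samples", "data.frame")
  d
}

#' Read camera-trap records
#'
#' Long format: one row per (site, year, taxon) with the number of
#' independent pictures, the number of distinct days with at least one
#' detection, and the active trap-days of the deployment.
#'
#' @param path CSV/TSV with columns `site_id`, `year`, `trap_days`,
#'   `taxon`, `n_pictures`, `n_detection_days`.
#' @return a validated `data.frame` of class `camera_records`.
#' @export
read_camera_records <- function(path) {
  d <- .read_table(path)
  need <- c("site_id", "year", "trap_days", "taxon", "n_pictures",
            "n_detection_days")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  camera_records(d)
}

#' Validate a camera-record table
#'
#' @param d data.frame with the columns documented in
#'   [read_camera_records()].
#' @return `d` with class `camera_records`.
#' @export
camera_records <- function(d) {
  if (any(d$trap_days <= 0)) stop("trap_days must be positive")
  if (any(d$n_pictures < 0)) stop("n_pictures must be >= 0")
  bad <- d$n_detection_days > d$trap_days | d$n_detection_days > d$n_pictures
  if (any(bad, na.rm = TRUE))
    stop("n_detection_days must not exceed trap_days or n_pictures (",
         paste(utils::head(paste(d$site_id[bad], d$taxon[bad]), 5),
               collapse = "; "), ")")
  class(d) <- unique(c("camera_records", class(d)))
  d
}

.cost_components <- c("reusable", "single_use", "labour_lab", "logistics")

#' Build a one-row survey cost model
#'
#' Four budget components (reusable equipment, single-use equipment,
#' labour + lab work, logistics) per survey method and year.  The total is
#' the component sum unless an explicit `total` is supplied, in which case
#' the explicit value takes precedence (with a warning when the two
#' disagree by more than one dollar).  Per-unit cost is the total divided
#' by the number of samples or camera sites, rounded half-up to the
#' nearest dollar.
#'
#' @param method `"camera"` or `"edna"`.
#' @param year survey year.
#' @param reusable,single_use,labour_lab,logistics component costs, USD.
#' @param n_units number of eDNA samples or camera sites.
#' @param total optional explicit total cost, USD.
#' @return one-row `data.frame` of class `cost_table` with `total` and
#'   `per_unit` filled in.
#' @export
cost_model <- function(method, year, reusable, single_use, labour_lab,
                       logistics, n_units, total = NULL) {
  d <- data.frame(method = method, year = year, reusable = reusable,
                  single_use = single_use, labour_lab = labour_lab,
                  logistics = logistics, n_units = n_units,
                  total = if (is.null(total)) NA_real_ else total,
                  stringsAsFactors = FALSE)
  .finalize_cost_table(d)
}

.finalize_cost_table <- function(d) {
  comp <- as.matrix(d[.cost_components])
  if (any(comp < 0, na.rm = TRUE)) stop("negative cost component")
  if (any(d$n_units <= 0)) stop("n_units must be positive")
  comp_sum <- rowSums(comp)
  if (!"total" %in% names(d)) d$total <- NA_real_
  explicit <- !is.na(d$total)
  off <- explicit & abs(d$total - comp_sum) > 1
  if (any(off))
    warning("explicit total differs from component sum by > $1 for: ",
            paste(d$method[off], d$year[off], collapse = "; "),
            " (explicit total kept)")
  d$total[!explicit] <- comp_sum[!explicit]
  if (any(d$total < 0)) stop("negative total cost")
  d$per_unit <- round_half_up(d$total / d$n_units)
  class(d) <- c("cost_table", "data.frame")
  d
}

#' Read a survey cost table
#'
#' Expects columns `method`, `year`, `reusable`, `single_use`,
#' `labour_lab`, `logistics`, `n_units` and optionally `total`.  See
#' [cost_model()] for the total/per-unit rules.
#'
#' @param path CSV/TSV path.
#' @return a `data.frame` of class `cost_table`.
#' @export
read_cost_model <- function(path) {
  d <- .read_table(path)
  need <- c("method", "year", .cost_components, "n_units")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  .finalize_cost_table(d)
}
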