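#' Substitute root masses below the balance detection limit
#'
#' A balance with 0.1 mg accuracy cannot weigh roots lighter than its
#' detection limit. Following the standard half-limit convention, any root
#' mass strictly below `limit_mg` is replaced by `limit_mg / 2` (0.05 mg at
#' the default limit); masses at or above the limit pass through unchanged.
#'
#' @param root_mass_mg Numeric vector of non-negative root masses in mg.
#' @param limit_mg Detection limit of the balance in mg (default 0.1).
#' @return Numeric vector of substituted masses, with attribute
#'   `below_detection`, a logical vector flagging which entries were
#'   substituted.
#' @examples
#' apply_detection_limit(c(0.03, 0.1, 5.2))
#' @export
apply_detection_limit <- function(root_mass_mg, limit_mg = 0.1) {
  stopifnot(is.numeric(root_mass_mg), is.numeric(limit_mg), length(limit_mg) == 1L)
  if (limit_mg <= 0) stop("`limit_mg` must be positive")
  if (any(!is.finite(root_mass_mg)) || any(root_mass_mg < 0))
    stop("root masses must be finite and non-negative")
  below <- root_mass_mg < limit_mg
  out <- ifelse(below, limit_mg / 2, root_mass_mg)
  attr(out, "below_detection") <- below
  out
}

#' Total biomass of a plant
#'
#' Sum of root and shoot dry mass, in mg.
#'
#' @param root_mass_mg,shoot_mass_mg Non-negative masses in mg.
#' @return Numeric vector of totals in mg.
#' @export
compute_total_biomass <- function(root_mass_mg, shoot_mass_mg) {
  if (any(root_mass_mg < 0) || any(shoot_mass_mg < 0))
    stop("masses must be non-negative")
  root_mass_mg + shoot_mass_mg
}

#' Root:shoot biomass ratio
#'
#' Belowground divided by aboveground dry mass. The root mass is expected to
#' have already been through [apply_detection_limit()], so it is strictly
#' positive.
#'
#' @param root_mass_mg Positive root mass in mg (after detection-limit
#'   substitution).
#' @param shoot_mass_mg Strictly positive shoot mass in mg.
#' @return Dimensionless positive ratio.
#' @export
compute_root_shoot_ratio <- function(root_mass_mg, shoot_mass_mg) {
  if (any(shoot_mass_mg <= 0))
    stop("shoot mass must be strictly positive; the ratio is undefined at 0")
  if (any(root_mass_mg < 0)) stop("root mass must be non-negative")
  root_mass_mg / shoot_mass_mg
}

#' Natural-log response transform
#'
#' The model's responses are the natural log of total biomass in grams and
#' the natural log of the (dimensionless) root:shoot ratio. Masses are stored
#' in mg throughout the package, so `kind = "total_biomass_mg"` divides by
#' 1000 before taking the log.
#'
#' @param value Positive numeric vector.
#' @param kind `"total_biomass_mg"` (mg in, log grams out) or `"ratio"`.
#' @return Numeric vector of log responses.
#' @examples
#' log_response(1000, "total_biomass_mg")  # ln(1 g) = 0
#' @export
log_response <- function(value, kind = c("total_biomass_mg", "ratio")) {
  kind <- match.arg(kind)
  if (any(!is.finite(value)) || any(value <= 0))
    stop("log response requires strictly positive finite values")
  if (kind == "total_biomass_mg") log(value / 1000) else log(value)
}

.pot_levels <- c("regular", "flat")
.nutrient_levels <- c("water", "fertilized")

#' Validate a table of per-plant biomass records
#'
#' Checks the record table the rest of the pipeline consumes: one row per
#' harvested plant with its species label, pot type (`regular` or `flat`),
#' nutrient treatment (`water` or `fertilized`) and root/shoot dry masses in
#' mg. A `root_below_detection` flag column is accepted and must agree with
#' the stored mass being below `limit_mg`; if absent it is derived.
#'
#' @param records A data.frame with columns `species_id`, `pot_type`,
#'   `nutrient`, `root_mass_mg`, `shoot_mass_mg` and optionally
#'   `root_below_detection`.
#' @param limit_mg Balance detection limit in mg.
#' @return The validated data.frame with a `root_below_detection` column.
#' @export
validate_biomass_records <- function(records, limit_mg = 0.1) {
  required <- c("species_id", "pot_type", "nutrient", "root_mass_mg", "shoot_mass_mg")
  missing <- setdiff(required, names(records))
  if (length(missing))
    stop("missing required columns: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(records), c(required, "root_below_detection"))
  if (length(extra))
    warning("ignoring unknown columns: ", paste(extra, collapse = ", "))
  if (nrow(records) == 0L) stop("no records")
  bad_pot <- setdiff(unique(as.character(records$pot_type)), .pot_levels)
  if (length(bad_pot))
    stop("pot_type must be one of {regular, flat}; found: ",
         paste(bad_pot, collapse = ", "))
  bad_nut <- setdiff(unique(as.character(records$nutrient)), .nutrient_levels)
  if (length(bad_nut))
    stop("nutrient must be one of {water, fertilized}; found: ",
         paste(bad_nut, collapse = ", "))
  if (any(!is.finite(records$root_mass_mg)) || any(records$root_mass_mg < 0))
    stop("root_mass_mg must be finite and >= 0")
  if (any(!is.finite(records$shoot_mass_mg)) || any(records$shoot_mass_mg <= 0))
    stop("shoot_mass_mg must be finite and > 0")
  below <- records$root_mass_mg < limit_mg
  if (!is.null(records$root_below_detection)) {
    if (!identical(as.logical(records$root_below_detection), below))
      stop("root_below_detection flag disagrees with stored root masses")
  }
  records$root_below_detection <- below
  records
}

#' Read per-plant biomass records from a CSV file
#'
#' @param path Path to a CSV file with a header row and columns `species_id`,
#'   `pot_type`, `nutrient`, `root_mass_mg`, `shoot_mass_mg`.
#' @param limit_mg Balance detection limit in mg.
#' @return A validated record data.frame (see [validate_biomass_records()]).
#' @export
read_biomass_csv <- function(path, limit_mg = 0.1) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_biomass_records(records, limit_mg = limit_mg)
}

#' Prepare model-ready responses and design indicators
#'
#' Turns validated records into the quantities the hierarchical model sees:
#' treatment indicators P (1 = flat pot) and N (1 = fertilized), species
#' indices aligned to a fixed species ordering (normally the tree's tip
#' order), and both log responses per plant. Detection-limit substitution is
#' applied to the root mass before the ratio; by default the substituted
#' value also enters total biomass (the difference is at most half the limit,
#' negligible against shoot mass) so each plant has one consistent mass pair
#' — set `substitute_in_total = FALSE` to use the raw root mass there.
#'
#' @param records Record data.frame (see [validate_biomass_records()]).
#' @param species_order Character vector of species labels fixing the index
#'   order; every `species_id` must appear in it.
#' @param exclude_below_detection Drop plants whose root mass was below the
#'   detection limit (the sensitivity re-analysis) instead of substituting.
#' @param limit_mg Balance detection limit in mg.
#' @param substitute_in_total Use the substituted root mass in total biomass
#'   too (default `TRUE`).
#' @return An object of class `prepared_dataset`: a list with `data` (one row
#'   per retained plant: `species_index`, `species_id`, `P`, `N`,
#'   `log_total_biomass`, `log_root_shoot`, `root_below_detection`) and
#'   `species_order`.
#' @export
prepare_dataset <- function(records, species_order,
                            exclude_below_detection = FALSE,
                            limit_mg = 0.1,
                            substitute_in_total = TRUE) {
  records <- validate_biomass_records(records, limit_mg = limit_mg)
  if (anyDuplicated(species_order)) stop("species_order has duplicate labels")
  if (length(species_order) < 2L) stop("need at least 2 species")
  unknown <- setdiff(unique(records$species_id), species_order)
  if (length(unknown))
    stop("species not in species_order: ", paste(unknown, collapse = ", "))

  root_sub <- apply_detection_limit(records$root_mass_mg, limit_mg)
  below <- attr(root_sub, "below_detection")
  if (exclude_below_detection) {
    keep <- !below
    if (!any(keep)) stop("all records excluded: every root mass below the limit")
    records <- records[keep, , drop = FALSE]
    root_sub <- root_sub[keep]
    below <- below[keep]
  }
  root_for_total <- if (substitute_in_total) as.numeric(root_sub) else records$root_mass_mg
  total <- compute_total_biomass(root_for_total, records$shoot_mass_mg)
  ratio <- compute_root_shoot_ratio(as.numeric(root_sub), records$shoot_mass_mg)

  data <- data.frame(
    species_index = match(records$species_id, species_order),
    species_id = records$species_id,
    P = as.integer(records$pot_type == "flat"),
    N = as.integer(records$nutrient == "fertilized"),
    log_total_biomass = log_response(total, "total_biomass_mg"),
    log_root_shoot = log_response(ratio, "ratio"),
    root_below_detection = below,
    stringsAsFactors = FALSE
  )
  structure(list(data = data, species_order = species_order),
            class = "prepared_dataset")
}

#' @export
print.prepared_dataset <- function(x, ...) {
  cat(sprintf("prepared_dataset: %d plants, %d species, %d below detection limit\n",
              nrow(x$data), length(x$species_order),
              sum(x$data$root_below_detection)))
  invisible(x)
}

#' Write a prepared dataset to CSV for audit
#'
#' @param prepared A `prepared_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_prepared_csv <- function(prepared, path) {
  stopifnot(inherits(prepared, "prepared_dataset"))
  utils::write.csv(prepared$data, path, row.names = FALSE)
  invisible(path)
}
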