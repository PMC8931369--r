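# Dataset assembly: unit conversion, species averaging, log transform,
# density cross-checks, and the olfactory-bulb / striatum imputation used
# to harmonize mammalian brain divisions.

BRAIN_TISSUE_DENSITY <- 1.036  # g per cm^3

#' Convert endocranial volume to brain mass
#'
#' @param volume_cm3 endocranial volume(s) in cm^3.
#' @return brain mass in g (`volume * 1.036`).
#' @export
endocast_to_mass <- function(volume_cm3) volume_cm3 * BRAIN_TISSUE_DENSITY

#' Assemble a species-level analysis table from raw measurements
#'
#' Takes a long table of individual measurements (columns `species`,
#' `trait`, `value`, `unit`), converts volumes to masses using the density
#' of brain tissue (1.036 g/cm^3), averages individuals per species
#' (average-then-log by default), log10-transforms, and optionally matches
#' the result to a tree (pruning both sides with a warning). Provenance
#' per species-trait value (`measured` vs `converted_from_volume`) is kept
#' alongside. If matching `<part>_neurons` / `<part>_mass` /
#' `<part>_density` traits are present, the density is recomputed as
#' neurons per gram and discrepancies > 1% raise a warning.
#'
#' @param measurements long tibble: `species`, `trait`, `value`, `unit`
#'   (`"g"`, `"cm3"`, or `"count"`).
#' @param tree optional `phylo` to match against.
#' @param average `"mean-then-log"` (default) or `"log-then-mean"`.
#' @param species species column name.
#' @return an `assembled_dataset`: list with `data` (wide tibble of
#'   `log_<trait>` columns), `provenance` (long tibble), and `tree`.
#' @export
assemble_dataset <- function(measurements, tree = NULL,
                             average = c("mean-then-log", "log-then-mean"),
                             species = "species") {
  average <- match.arg(average)
  m <- tibble::as_tibble(measurements)
  need <- c(species, "trait", "value", "unit")
  if (!all(need %in% names(m))) {
    stop("measurements need columns: ", paste(need, collapse = ", "))
  }
  if (anyNA(m$unit) || any(m$unit == "")) stop("unit-less measurement rows present")
  bad <- setdiff(unique(m$unit), c("g", "cm3", "count"))
  if (length(bad)) stop("unknown unit(s): ", paste(bad, collapse = ", "))
  m[[species]] <- normalize_labels(as.character(m[[species]]))
  m <- dplyr::mutate(
    m,
    provenance = ifelse(.data$unit == "cm3", "converted_from_volume", "measured"),
    value = ifelse(.data$unit == "cm3", endocast_to_mass(.data$value), .data$value)
  )
  if (any(m$value <= 0)) stop("non-positive measurement values")
  per_species <- m |>
    dplyr::group_by(.data[[species]], .data$trait) |>
    dplyr::summarise(
      log_value = if (average == "mean-then-log") {
        log10(mean(.data$value))
      } else {
        mean(log10(.data$value))
      },
      n_individuals = dplyr::n(),
      provenance = paste(sort(unique(.data$provenance)), collapse = "+"),
      .groups = "drop"
    )
  wide <- per_species |>
    dplyr::mutate(trait = paste0("log_", .data$trait)) |>
    tidyr::pivot_wider(id_cols = dplyr::all_of(species),
                       names_from = "trait", values_from = "log_value")
  check_density_columns(wide)
  if (!is.null(tree)) {
    md <- match_tree_data(wide, tree, species, min_species = 2L)
    wide <- md$data
    tree <- md$tree
  }
  structure(list(data = wide, provenance = per_species, tree = tree),
            class = "assembled_dataset")
}

# recompute <part>_density = <part>_neurons / <part>_mass where all three
# are present; warn on > 1% relative disagreement (log10 scale)
check_density_columns <- function(wide) {
  dens <- grep("^log_(.+)_density$", names(wide), value = TRUE)
  for (d in dens) {
    part <- sub("^log_(.+)_density$", "\\1", d)
    nc <- paste0("log_", part, "_neurons")
    mc <- paste0("log_", part, "_mass")
    if (all(c(nc, mc) %in% names(wide))) {
      recomputed <- wide[[nc]] - wide[[mc]]
      off <- abs(10^(wide[[d]] - recomputed) - 1) > 0.01
      if (any(off, na.rm = TRUE)) {
        warning(sum(off, na.rm = TRUE), " ", part,
                " density value(s) disagree with neurons/mass by > 1%")
      }
    }
  }
  invisible(wide)
}

#' @export
print.assembled_dataset <- function(x, ...) {
  cat("Assembled dataset:", nrow(x$data), "species,",
      ncol(x$data) - 1L, "log10 trait column(s)\n")
  print(utils::head(x$data))
  invisible(x)
}

#' Impute olfactory-bulb and striatal values and harmonize brain divisions
#'
#' Mammalian datasets often exclude the olfactory bulb (OB) from the
#' telencephalon and count the striatum with the rest of brain. This
#' operation (i) fills missing OB mass and neuron numbers from
#' clade-specific log10 allometries on brain mass, (ii) estimates striatal
#' mass as brain mass times the group's mean striatal proportion,
#' (iii) derives striatal neurons from the species' own telencephalic
#' neuron density, and (iv) reassigns the striatum from the rest of brain
#' to the telencephalon, with every change recorded in an audit table.
#' Species with measured OB values are left untouched.
#'
#' @param data tibble with one row per species: `species`, `group`,
#'   `brain_mass`, `tel_mass`, `tel_neurons`, `rest_mass`, `rest_neurons`,
#'   and optionally measured `ob_mass`, `ob_neurons` (NA when missing).
#'   Masses in g, neurons as counts (linear scale, not log).
#' @param ob_rules tibble of clade scaling rules: `group`,
#'   `mass_intercept`, `mass_slope`, `neurons_intercept`, `neurons_slope`
#'   (log10 OB mass/neurons against log10 brain mass).
#' @param striatum_proportions tibble: `group`, `proportion` (striatal
#'   fraction of brain mass).
#' @return list with `data` (corrected table, imputed values flagged in
#'   `ob_imputed` and `striatum_imputed`) and `audit` (per-species
#'   changes).
#' @export
impute_ob_striatum <- function(data, ob_rules = NULL,
                               striatum_proportions = NULL) {
  d <- tibble::as_tibble(data)
  need <- c("species", "group", "brain_mass", "tel_mass", "tel_neurons",
            "rest_mass", "rest_neurons")
  if (!all(need %in% names(d))) {
    stop("data needs columns: ", paste(need, collapse = ", "))
  }
  if (!"ob_mass" %in% names(d)) d$ob_mass <- NA_real_
  if (!"ob_neurons" %in% names(d)) d$ob_neurons <- NA_real_
  d$ob_imputed <- FALSE
  d$striatum_imputed <- FALSE
  # (i) OB from clade allometry where missing
  if (!is.null(ob_rules)) {
    for (i in which(is.na(d$ob_mass) | is.na(d$ob_neurons))) {
      r <- ob_rules[ob_rules$group == d$group[i], ]
      if (nrow(r) != 1L) next
      lb <- log10(d$brain_mass[i])
      if (is.na(d$ob_mass[i])) {
        d$ob_mass[i] <- 10^(r$mass_intercept + r$mass_slope * lb)
      }
      if (is.na(d$ob_neurons[i])) {
        d$ob_neurons[i] <- 10^(r$neurons_intercept + r$neurons_slope * lb)
      }
      d$ob_imputed[i] <- TRUE
    }
  }
  miss <- is.na(d$ob_mass) | is.na(d$ob_neurons)
  if (any(miss)) {
    warning(sum(miss), " species left without OB values (no clade rule)")
  }
  tel_neurons_before <- d$tel_neurons
  rest_neurons_before <- d$rest_neurons
  # OB counted with the telencephalon where it had been excluded
  add_ob <- d$ob_imputed & !is.na(d$ob_neurons)
  d$tel_neurons[add_ob] <- d$tel_neurons[add_ob] + d$ob_neurons[add_ob]
  d$tel_mass[add_ob] <- d$tel_mass[add_ob] + d$ob_mass[add_ob]
  # (ii)-(iv) striatum moved rest-of-brain -> telencephalon
  if (!is.null(striatum_proportions)) {
    prop <- stats::setNames(striatum_proportions$proportion,
                            striatum_proportions$group)
    has <- d$group %in% names(prop)
    if (any(!has)) {
      warning(sum(!has), " species lack a striatal proportion; left unchanged")
    }
    str_mass <- ifelse(has, d$brain_mass * unname(prop[d$group]), NA_real_)
    tel_density <- d$tel_neurons / d$tel_mass
    str_neurons <- str_mass * tel_density
    ok <- has & !is.na(str_neurons)
    d$striatum_mass <- ifelse(ok, str_mass, NA_real_)
    d$striatum_neurons <- ifelse(ok, str_neurons, NA_real_)
    d$tel_neurons[ok] <- d$tel_neurons[ok] + str_neurons[ok]
    d$tel_mass[ok] <- d$tel_mass[ok] + str_mass[ok]
    d$rest_neurons[ok] <- d$rest_neurons[ok] - str_neurons[ok]
    d$rest_mass[ok] <- d$rest_mass[ok] - str_mass[ok]
    d$striatum_imputed[ok] <- TRUE
  }
  audit <- tibble::tibble(
    species = d$species,
    tel_neurons_change = d$tel_neurons / tel_neurons_before - 1,
    rest_neurons_change = d$rest_neurons / rest_neurons_before - 1,
    ob_imputed = d$ob_imputed, striatum_imputed = d$striatum_imputed
  )
  list(data = d, audit = audit)
}
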