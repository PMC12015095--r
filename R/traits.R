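# Species traits: sexual size dimorphism and body size from male/female
# masses, and the species-level analysis table joining traits to HRE counts.

#' Sexual size dimorphism from male and female body mass
#'
#' SSD is the natural log of the male/female body-mass ratio: positive values
#' are male-larger, negative female-larger, and the measure is antisymmetric
#' under swapping the sexes.
#'
#' @param male_mass,female_mass Positive masses in the same units (vectorized).
#' @return `ln(male_mass / female_mass)`.
#' @examples
#' compute_ssd(2, 1) # ln 2
#' @export
compute_ssd <- function(male_mass, female_mass) {
  if (any(!is.finite(male_mass)) || any(!is.finite(female_mass)) ||
      any(male_mass <= 0) || any(female_mass <= 0)) {
    stop("body masses must be finite and positive", call. = FALSE)
  }
  log(male_mass / female_mass)
}

#' Read a species trait table
#'
#' CSV with columns `species`, `male_mass`, `female_mass` and optionally
#' `order` and `contig_n50`. Masses are kilograms internally; use
#' `mass_unit = "g"` to convert gram-scale inputs.
#'
#' @param path CSV path.
#' @param mass_unit `"kg"` (default) or `"g"`.
#' @return Data frame with `ssd` and `body_size` (arithmetic mean of the two
#'   masses) added.
#' @export
read_traits <- function(path, mass_unit = c("kg", "g")) {
  mass_unit <- match.arg(mass_unit)
  stopifnot(file.exists(path))
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("species", "male_mass", "female_mass")
  missing_cols <- setdiff(required, names(tr))
  if (length(missing_cols) > 0L) {
    stop(sprintf("trait file missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (mass_unit == "g") {
    tr$male_mass <- tr$male_mass / 1000
    tr$female_mass <- tr$female_mass / 1000
  }
  tr$ssd <- compute_ssd(tr$male_mass, tr$female_mass)
  tr$body_size <- (tr$male_mass + tr$female_mass) / 2
  tr
}

#' Assemble the species-level analysis table
#'
#' Inner-joins the trait table to the per-species count table, restricts to
#' species present among the tree tips, and adds the natural-log columns the
#' models use (`ln_are`, `ln_ere`, `ln_body`). Species with a zero count in
#' either class are excluded with a warning, since a zero cannot be
#' log-transformed. Exclusion counts at every step are reported via
#' `message()`.
#'
#' @param traits Trait data frame (from [read_traits()] or equivalent; must
#'   contain `species`, `male_mass`, `female_mass`).
#' @param counts Data frame with `species`, `are_count`, `ere_count` and
#'   optionally `flank`, `interrogated_bp`.
#' @param tip_labels Character vector of phylogeny tip labels.
#' @param quiet Suppress the step-by-step exclusion messages.
#' @return Data frame, one row per retained species.
#' @export
build_species_table <- function(traits, counts, tip_labels, quiet = FALSE) {
  stopifnot(is.data.frame(traits), is.data.frame(counts))
  for (nm in c("species", "male_mass", "female_mass")) {
    if (!nm %in% names(traits)) stop(sprintf("traits missing column '%s'", nm), call. = FALSE)
  }
  for (nm in c("species", "are_count", "ere_count")) {
    if (!nm %in% names(counts)) stop(sprintf("counts missing column '%s'", nm), call. = FALSE)
  }
  if (anyDuplicated(traits$species)) stop("duplicated species in traits", call. = FALSE)
  if (anyDuplicated(counts$species)) stop("duplicated species in counts", call. = FALSE)

  if (!"ssd" %in% names(traits)) traits$ssd <- compute_ssd(traits$male_mass, traits$female_mass)
  if (!"body_size" %in% names(traits)) traits$body_size <- (traits$male_mass + traits$female_mass) / 2

  tab <- merge(traits, counts, by = "species")
  if (!quiet) {
    message(sprintf("join: %d trait x %d count rows -> %d shared species",
                    nrow(traits), nrow(counts), nrow(tab)))
  }
  on_tree <- tab$species %in% tip_labels
  if (!quiet && any(!on_tree)) {
    message(sprintf("dropped %d species absent from the tree", sum(!on_tree)))
  }
  tab <- tab[on_tree, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no species shared between traits, counts and tree", call. = FALSE)

  zero <- tab$are_count == 0 | tab$ere_count == 0
  if (any(zero)) {
    warning(sprintf("excluding %d species with a zero HRE count (cannot ln-transform): %s",
                    sum(zero), paste(tab$species[zero], collapse = ", ")), call. = FALSE)
    tab <- tab[!zero, , drop = FALSE]
  }
  tab$ln_are <- log(tab$are_count)
  tab$ln_ere <- log(tab$ere_count)
  tab$ln_body <- log(tab$body_size)
  rownames(tab) <- NULL
  tab
}
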