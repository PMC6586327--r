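#' Define a two-dimensional protein:carbohydrate diet
#'
#' Builds a chemically defined diet for 2-D nutritional-geometry assays.
#' Diets are standardized for total macronutrient concentration (default
#' 100 g/L) while the protein:carbohydrate ratio is manipulated, so that a
#' colony confined to the diet can only move along the corresponding
#' nutritional rail in (P, C) intake space.
#'
#' @param p_parts,c_parts Nonnegative ratio parts of protein and carbohydrate
#'   (e.g. `1, 6` for a 1:6 P:C diet). At least one must be positive.
#' @param total_conc Total macronutrient concentration in g/L (default 100).
#' @param label Diet label; defaults to `"p:c"` built from the parts.
#' @return An object of class `diet_2d`: a list with the parts, the total
#'   concentration, the per-nutrient concentrations `p_conc`/`c_conc` (g/L)
#'   and the dry-mass fractions `p_mass_frac`/`c_mass_frac`.
#' @examples
#' diet_2d(1, 6)            # 14.29 g/L protein, 85.71 g/L carbohydrate
#' diet_2d(1, 1, total_conc = 100)
#' @export
diet_2d <- function(p_parts, c_parts, total_conc = 100, label = NULL) {
  if (p_parts < 0 || c_parts < 0)
    stop("invalid ratio: diet parts must be nonnegative", call. = FALSE)
  if (p_parts + c_parts <= 0)
    stop("invalid ratio: at least one of p_parts, c_parts must be positive",
         call. = FALSE)
  if (total_conc <= 0)
    stop("total_conc must be positive", call. = FALSE)
  if (is.null(label)) label <- paste0(p_parts, ":", c_parts)
  s <- p_parts + c_parts
  structure(list(
    label       = label,
    p_parts     = p_parts,
    c_parts     = c_parts,
    total_conc  = total_conc,
    p_conc      = total_conc * p_parts / s,
    c_conc      = total_conc * c_parts / s,
    p_mass_frac = p_parts / s,
    c_mass_frac = c_parts / s
  ), class = "diet_2d")
}

#' @export
print.diet_2d <- function(x, ...) {
  cat(sprintf("2-D diet %s: %.4g g/L protein + %.4g g/L carbohydrate (total %g g/L)\n",
              x$label, x$p_conc, x$c_conc, x$total_conc))
  invisible(x)
}

#' Define a three-dimensional protein:carbohydrate:lipid diet
#'
#' Builds a diet for right-angled mixture-triangle (RMT) experiments. Diets
#' are standardized for total energy content (default 675 J) while the
#' fraction of that energy supplied by each macronutrient is manipulated.
#' Dry masses are derived using an energy density `energy_density` J/mg for
#' protein and carbohydrate and twice that for lipid (lipids carry roughly
#' twice the energy per unit mass).
#'
#' The label `"33:33:33"` is accepted as shorthand for exact thirds via
#' `diet_3d(100/3, 100/3, 100/3)`; printed fraction triples must otherwise
#' sum to 100.
#'
#' @param p_frac,c_frac,l_frac Percent of total macronutrient energy supplied
#'   by protein, carbohydrate and lipid; must be nonnegative and sum to 100
#'   (tolerance 1e-6).
#' @param total_energy Total energy content in joules (default 675).
#' @param energy_density Energy density of protein and carbohydrate in J per
#'   mg dry mass (default 17, i.e. about 4 kcal/g); lipid uses twice this.
#' @param label Diet label; defaults to `"p:c:l"` from rounded fractions.
#' @return An object of class `diet_3d` with the energy fractions, the
#'   per-nutrient energies (J), dry masses (mg) and dry-mass fractions.
#' @examples
#' diet_3d(10, 10, 80)                 # 67.5 J P, 67.5 J C, 540 J L
#' diet_3d(100 / 3, 100 / 3, 100 / 3)  # balanced thirds
#' @export
diet_3d <- function(p_frac, c_frac, l_frac, total_energy = 675,
                    energy_density = 17, label = NULL) {
  fr <- c(p_frac, c_frac, l_frac)
  if (any(fr < 0))
    stop("composition error: energy fractions must be nonnegative", call. = FALSE)
  if (abs(sum(fr) - 100) > 1e-6)
    stop(sprintf("composition error: fractions sum to %.6f, not 100", sum(fr)),
         call. = FALSE)
  if (total_energy <= 0)
    stop("total_energy must be positive", call. = FALSE)
  if (is.null(label))
    label <- paste(round(fr), collapse = ":")
  energy <- fr / 100 * total_energy
  dens   <- c(energy_density, energy_density, 2 * energy_density)
  mass   <- energy / dens
  names(energy) <- names(mass) <- c("P", "C", "L")
  structure(list(
    label              = label,
    p_frac             = p_frac,
    c_frac             = c_frac,
    l_frac             = l_frac,
    total_energy       = total_energy,
    energy_density     = energy_density,
    energy_per_nutrient = energy,
    mass_per_nutrient  = mass,
    mass_frac          = mass / sum(mass)
  ), class = "diet_3d")
}

#' @export
print.diet_3d <- function(x, ...) {
  cat(sprintf("3-D diet %s: %.4g%% P, %.4g%% C, %.4g%% L of %g J total energy\n",
              x$label, x$p_frac, x$c_frac, x$l_frac, x$total_energy))
  cat(sprintf("  energy (J): P %.4g, C %.4g, L %.4g; dry mass (mg): P %.4g, C %.4g, L %.4g\n",
              x$energy_per_nutrient[1], x$energy_per_nutrient[2],
              x$energy_per_nutrient[3], x$mass_per_nutrient[1],
              x$mass_per_nutrient[2], x$mass_per_nutrient[3]))
  invisible(x)
}

#' Right-angled mixture-triangle coordinates of a 3-D diet
#'
#' Maps a protein:carbohydrate:lipid composition to the RMT plane: protein on
#' the x axis, carbohydrate on the y axis, and the implicit lipid fraction as
#' a negative-slope isocline `x + y = 100 - l_frac`. The mapping is
#' invertible: `(x, y)` recovers the composition as `(x, y, 100 - x - y)`.
#'
#' @param diet A [diet_3d()] object.
#' @return A list with `x`, `y` (percent) and `isocline_sum = 100 - l_frac`,
#'   the value of `x + y` along the lipid isocline through the diet.
#' @examples
#' rmt_coordinates(diet_3d(10, 10, 80))  # (10, 10), isocline x + y = 20
#' @export
rmt_coordinates <- function(diet) {
  stopifnot(inherits(diet, "diet_3d"))
  list(x = diet$p_frac, y = diet$c_frac, isocline_sum = 100 - diet$l_frac)
}

#' Nutritional rail for a fixed P:C diet
#'
#' The rail is the ray from the origin of (protein, carbohydrate) intake
#' space along which a colony confined to a single diet of ratio
#' `p_parts:c_parts` must move; any point `t * direction` (t > 0) has exactly
#' that P:C ratio.
#'
#' @inheritParams diet_2d
#' @return An object of class `nutritional_rail` with the parts and the unit
#'   `direction` vector `(p_parts, c_parts) / ||(p_parts, c_parts)||`.
#' @examples
#' nutritional_rail(1, 1)  # direction (0.7071, 0.7071)
#' @export
nutritional_rail <- function(p_parts, c_parts) {
  if (p_parts < 0 || c_parts < 0)
    stop("invalid ratio: rail parts must be nonnegative", call. = FALSE)
  if (p_parts == 0 && c_parts == 0)
    stop("invalid ratio: rail 0:0 is undefined", call. = FALSE)
  v <- c(p_parts, c_parts)
  structure(list(
    p_parts = p_parts, c_parts = c_parts,
    direction = v / sqrt(sum(v^2))
  ), class = "nutritional_rail")
}

#' @export
print.nutritional_rail <- function(x, ...) {
  cat(sprintf("nutritional rail %g:%g P:C, direction (%.5f, %.5f)\n",
              x$p_parts, x$c_parts, x$direction[1], x$direction[2]))
  invisible(x)
}

#' Construct an experiment design
#'
#' @param kind One of `"choice_2d"`, `"nochoice_2d"`, `"nochoice_3d"`.
#' @param treatments For no-choice designs, a list of diets; for choice
#'   designs, a list of length-2 lists pairing two distinct diets.
#' @param replicates Colonies per treatment.
#' @param n_workers Initial workers per colony.
#' @param n_days Experiment duration in days.
#' @param n_queens Queens per colony.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(kind, treatments, replicates, n_workers = 200,
                              n_days = 12, n_queens = 0) {
  kind <- match.arg(kind, c("choice_2d", "nochoice_2d", "nochoice_3d"))
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (kind == "choice_2d") {
    ok <- vapply(treatments, function(tr)
      is.list(tr) && length(tr) == 2 &&
        !identical(tr[[1]]$label, tr[[2]]$label), logical(1))
    if (!all(ok))
      stop("choice treatments must each pair two distinct diets", call. = FALSE)
  }
  structure(list(
    kind       = kind,
    treatments = treatments,
    replicates = replicates,
    n_workers  = n_workers,
    n_days     = n_days,
    n_queens   = n_queens
  ), class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("%s design: %d treatments x %d colonies (%d total), %d workers, %d days\n",
              x$kind, length(x$treatments), x$replicates, n_colonies(x),
              x$n_workers, x$n_days))
  invisible(x)
}

#' Total number of colonies in a design
#' @param design An [experiment_design()] object.
#' @return Integer colony count (treatments x replicates).
#' @export
n_colonies <- function(design) {
  length(design$treatments) * design$replicates
}

#' Standard diet series
#'
#' `diets_2d_standard()` returns the five 2-D P:C diets (1:6, 1:3, 1:1, 3:1,
#' 6:1 at 100 g/L total). `diets_3d_standard()` returns the seven 3-D P:C:L
#' diets (33:33:33 as exact thirds, the three 80/10/10 corners and the three
#' 45/45/10 mid-edge blends, all at 675 J).
#'
#' @return A named list of [diet_2d()] or [diet_3d()] objects.
#' @export
diets_2d_standard <- function() {
  parts <- list(c(1, 6), c(1, 3), c(1, 1), c(3, 1), c(6, 1))
  out <- lapply(parts, function(p) diet_2d(p[1], p[2]))
  names(out) <- vapply(out, `[[`, character(1), "label")
  out
}

#' @rdname diets_2d_standard
#' @export
diets_3d_standard <- function() {
  fr <- list(
    "33:33:33" = c(100, 100, 100) / 3,
    "80:10:10" = c(80, 10, 10),
    "10:80:10" = c(10, 80, 10),
    "10:10:80" = c(10, 10, 80),
    "45:45:10" = c(45, 45, 10),
    "10:45:45" = c(10, 45, 45),
    "45:10:45" = c(45, 10, 45)
  )
  out <- Map(function(f, lab) diet_3d(f[1], f[2], f[3], label = lab),
             fr, names(fr))
  out
}

#' The three study designs
#'
#' Returns the experiment designs used throughout the package's worked
#' analyses: a 2-D choice design (two diet pairings, 1:6 vs 3:1 and 1:3 vs
#' 6:1 P:C, 12 colonies each over 12 days), a 2-D no-choice design (five P:C
#' diets, 8 colonies each over 12 days) and a 3-D no-choice design (seven
#' P:C:L diets, 5 colonies each with 4 queens over 14 days). Colonies start
#' with 200 workers.
#'
#' @param analyzable If `TRUE`, the choice design uses 11 replicates per
#'   pairing (the analyzable count after one colony per pairing is dropped
#'   for missing intake data) instead of the 12 assembled.
#' @return A named list of three [experiment_design()] objects:
#'   `choice_2d`, `nochoice_2d`, `nochoice_3d`.
#' @examples
#' sapply(study_designs(), n_colonies)  # 24, 40, 35
#' @export
study_designs <- function(analyzable = FALSE) {
  d2 <- diets_2d_standard()
  pairings <- list(
    "1:6 vs 3:1" = list(d2[["1:6"]], d2[["3:1"]]),
    "1:3 vs 6:1" = list(d2[["1:3"]], d2[["6:1"]])
  )
  list(
    choice_2d = experiment_design("choice_2d", pairings,
                                  replicates = if (analyzable) 11 else 12,
                                  n_workers = 200, n_days = 12),
    nochoice_2d = experiment_design("nochoice_2d", diets_2d_standard(),
                                    replicates = 8, n_workers = 200,
                                    n_days = 12),
    nochoice_3d = experiment_design("nochoice_3d", diets_3d_standard(),
                                    replicates = 5, n_workers = 200,
                                    n_days = 14, n_queens = 4)
  )
}

#' Read or write diet recipe tables
#'
#' Recipes are stored as delimited text with columns
#' `(label, p_parts, c_parts)` for 2-D diets or
#' `(label, p_frac, c_frac, l_frac)` for 3-D diets.
#'
#' @param diets A named list of [diet_2d()] or [diet_3d()] objects.
#' @param path File path.
#' @return `write_diets` returns `path` invisibly; `read_diets` returns a
#'   named list of diet objects.
#' @export
write_diets <- function(diets, path) {
  stopifnot(length(diets) > 0)
  if (inherits(diets[[1]], "diet_2d")) {
    df <- data.frame(
      label   = vapply(diets, `[[`, character(1), "label"),
      p_parts = vapply(diets, `[[`, numeric(1), "p_parts"),
      c_parts = vapply(diets, `[[`, numeric(1), "c_parts"),
      total_conc = vapply(diets, `[[`, numeric(1), "total_conc")
    )
  } else {
    df <- data.frame(
      label  = vapply(diets, `[[`, character(1), "label"),
      p_frac = vapply(diets, `[[`, numeric(1), "p_frac"),
      c_frac = vapply(diets, `[[`, numeric(1), "c_frac"),
      l_frac = vapply(diets, `[[`, numeric(1), "l_frac"),
      total_energy = vapply(diets, `[[`, numeric(1), "total_energy")
    )
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_diets
#' @export
read_diets <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("p_parts" %in% names(df)) {
    out <- Map(function(l, p, c, tc) diet_2d(p, c, tc, label = l),
               df$label, df$p_parts, df$c_parts, df$total_conc)
  } else {
    out <- Map(function(l, p, c, f, te) diet_3d(p, c, f, te, label = l),
               df$label, df$p_frac, df$c_frac, df$l_frac, df$total_energy)
  }
  names(out) <- df$label
  out
}
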