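#' Fluid-chemistry conditions
#'
#' Bundles the in situ variables that define the reaction quotient:
#' temperature, per-species molalities, ionic strength, pH, and the
#' activity model. The proton activity is `10^(-pH)` and the solvent
#' activity is fixed at 1, so neither water nor H+ needs a concentration
#' entry.
#'
#' @param temperature Kelvin; must exceed 273 K.
#' @param concentrations Named numeric vector of molalities (mol/kg),
#'   all strictly positive.
#' @param pH Dimensionless.
#' @param ionic_strength mol/kg, non-negative. Only used by the `davies`
#'   activity model.
#' @param activity_model `"ideal"` (all activity coefficients 1, the
#'   default) or `"davies"`.
#' @param name Optional profile label carried through outputs.
#' @return Object of class `fluid_conditions`.
#' @export
fluid_conditions <- function(temperature, concentrations, pH,
                             ionic_strength = 0,
                             activity_model = c("ideal", "davies"),
                             name = NA_character_) {
  activity_model <- match.arg(activity_model)
  stopifnot(is.numeric(temperature), length(temperature) == 1L)
  if (temperature <= 273) stop("temperature must exceed 273 K")
  if (!is.numeric(concentrations) || is.null(names(concentrations))) {
    stop("concentrations must be a named numeric vector")
  }
  if (any(concentrations <= 0)) {
    stop("all concentrations must be strictly positive (log is taken)")
  }
  if (ionic_strength < 0) stop("ionic strength must be >= 0")
  structure(
    list(name = name, temperature = temperature,
         concentrations = concentrations, pH = pH,
         ionic_strength = ionic_strength,
         activity_model = activity_model),
    class = "fluid_conditions")
}

#' @export
print.fluid_conditions <- function(x, ...) {
  cat(sprintf("<fluid_conditions%s> T = %.2f K, pH %.2f, I = %.3g mol/kg, %s activities\n",
              if (is.na(x$name)) "" else paste0(" ", x$name),
              x$temperature, x$pH, x$ionic_strength, x$activity_model))
  print(x$concentrations)
  invisible(x)
}

#' Named fluid-chemistry profiles
#'
#' Loads a shipped condition profile by name. The `"jdfr"` profile
#' represents warm (64 degC = 337.15 K), anoxic, sulfate-rich (18 mM)
#' crustal fluid of the Juan de Fuca Ridge flank; its temperature and
#' sulfate molality are field-constrained while pH, ionic strength and the
#' remaining analyte molalities are documented placeholders, and any field
#' can be overridden through `...`.
#'
#' @param name Profile name (currently `"jdfr"`).
#' @param ... Overrides: `temperature`, `pH`, `ionic_strength`,
#'   `activity_model`, or any species name with a molality, e.g.
#'   `` `SO4-2` = 0.028 ``.
#' @param file Optional YAML profile file used instead of a shipped one.
#' @return A [fluid_conditions()] object.
#' @examples
#' fluid_profile("jdfr")$temperature            # 337.15
#' fluid_profile("jdfr", `SO4-2` = 0.028)$concentrations[["SO4-2"]]
#' @export
fluid_profile <- function(name = "jdfr", ..., file = NULL) {
  if (is.null(file)) {
    dir <- system.file("extdata", "profiles", package = "crustalbio",
                       mustWork = TRUE)
    known <- sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$"))
    if (!name %in% known) {
      stop("unknown profile '", name, "'; known profiles: ",
           paste(known, collapse = ", "))
    }
    file <- file.path(dir, paste0(name, ".yaml"))
  }
  y <- yaml::read_yaml(file)
  conc <- unlist(y$concentrations_mol_kg)
  fields <- list(temperature = y$temperature_K, pH = y$pH,
                 ionic_strength = y$ionic_strength_mol_kg,
                 activity_model = y$activity_model)
  dots <- list(...)
  for (key in names(dots)) {
    if (key %in% names(fields)) {
      fields[[key]] <- dots[[key]]
    } else {
      conc[[key]] <- dots[[key]]
    }
  }
  fluid_conditions(temperature = fields$temperature, concentrations = conc,
                   pH = fields$pH, ionic_strength = fields$ionic_strength,
                   activity_model = fields$activity_model,
                   name = y$name %||% name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standard Gibbs energy of reaction at temperature T
#'
#' At the reference temperature (298.15 K) this is the signed sum of the
#' participants' standard Gibbs energies of formation. At other
#' temperatures the Gibbs-Helmholtz (van 't Hoff) correction with constant
#' reaction enthalpy is applied:
#' `dG0(T) = (T/Tref) * dG0(Tref) + (1 - T/Tref) * dH0(Tref)`.
#'
#' @param reaction A `reaction` object.
#' @param species_tab A [species_table()] supplying `dGf0_kJ_mol` and
#'   `dHf0_kJ_mol` for every participant.
#' @param temperature Kelvin (> 273).
#' @return Standard Gibbs energy of reaction, kJ/mol.
#' @export
standard_gibbs <- function(reaction, species_tab, temperature = .T_REF) {
  stopifnot(inherits(reaction, "reaction"))
  if (temperature <= 273) stop("temperature must exceed 273 K")
  s <- reaction$stoichiometry
  unknown <- setdiff(names(s), rownames(species_tab))
  if (length(unknown)) {
    stop("unknown species: ", paste(unknown, collapse = ", "))
  }
  gf <- species_tab[names(s), "dGf0_kJ_mol"]
  hf <- species_tab[names(s), "dHf0_kJ_mol"]
  bad <- names(s)[!is.finite(gf) | !is.finite(hf)]
  if (length(bad)) {
    stop("missing formation properties for: ", paste(bad, collapse = ", "))
  }
  dG0 <- sum(s * gf)
  dH0 <- sum(s * hf)
  ratio <- temperature / .T_REF
  ratio * dG0 + (1 - ratio) * dH0
}

#' Single-ion activity coefficient
#'
#' `model = "ideal"` returns 1 for every species. `model = "davies"`
#' evaluates the Davies equation
#' `log10(gamma) = -A * z^2 * (sqrt(I)/(1 + sqrt(I)) - 0.3 * I)` with
#' A = 0.509 (the 298.15 K Debye-Huckel coefficient, held constant over
#' the moderate temperature range of interest). Neutral species and zero
#' ionic strength always give 1.
#'
#' @param charge Signed integer ion charge.
#' @param ionic_strength mol/kg, non-negative.
#' @param temperature Kelvin (accepted for interface symmetry; A is
#'   constant).
#' @param model `"ideal"` or `"davies"`.
#' @return Dimensionless activity coefficient.
#' @examples
#' activity_coefficient(-1, 0.1, model = "davies")  # ~0.754
#' @export
activity_coefficient <- function(charge, ionic_strength,
                                 temperature = .T_REF,
                                 model = c("ideal", "davies")) {
  model <- match.arg(model)
  if (ionic_strength < 0) stop("ionic strength must be >= 0")
  if (model == "ideal" || charge == 0 || ionic_strength == 0) {
    return(1)
  }
  A <- 0.509
  sI <- sqrt(ionic_strength)
  log10g <- -A * charge^2 * (sI / (1 + sI) - 0.3 * ionic_strength)
  10^log10g
}

# Activity of one participant under given conditions
.activity <- function(name, species_tab, conditions) {
  row <- species_tab[name, ]
  if (row$phase == "liquid-water") return(1)
  if (name == "H+") return(10^(-conditions$pH))
  m <- conditions$concentrations[name]
  if (is.na(m)) {
    stop("no concentration for species '", name, "' in conditions")
  }
  gamma <- activity_coefficient(row$charge, conditions$ionic_strength,
                                conditions$temperature,
                                conditions$activity_model)
  unname(gamma * m)
}

#' Natural-log reaction quotient
#'
#' `lnQ = sum(nu_i * ln(a_i))` with activities `a = gamma * m` for aqueous
#' solutes, `a(H2O) = 1`, and `a(H+) = 10^(-pH)`.
#'
#' @inheritParams standard_gibbs
#' @param conditions A [fluid_conditions()] object supplying a molality
#'   for every non-solvent, non-proton participant.
#' @return Dimensionless `lnQ`.
#' @export
reaction_quotient <- function(reaction, conditions, species_tab) {
  stopifnot(inherits(reaction, "reaction"),
            inherits(conditions, "fluid_conditions"))
  s <- reaction$stoichiometry
  unknown <- setdiff(names(s), rownames(species_tab))
  if (length(unknown)) {
    stop("unknown species: ", paste(unknown, collapse = ", "))
  }
  a <- vapply(names(s), .activity, numeric(1),
              species_tab = species_tab, conditions = conditions)
  sum(s * log(a))
}

#' In situ Gibbs energy of a catabolic reaction
#'
#' Combines the temperature-corrected standard Gibbs energy with the
#' reaction quotient, `dG = dG0(T) + R*T*lnQ`, and normalizes per mole of
#' electrons transferred so that reactions of different stoichiometry are
#' comparable on a common energy-yield scale.
#'
#' @inheritParams reaction_quotient
#' @return Object of class `energy_result` with fields `reaction_id`,
#'   `donor`, `n_electrons`, `temperature_K`, `dG0_T`, `lnQ`, `dG`, and
#'   `dG_per_electron` (kJ per mol electron).
#' @examples
#' sp <- species_table()
#' rx <- shipped_reactions()
#' gibbs_energy(rx$co_sulfate, fluid_profile("jdfr"), sp)
#' @export
gibbs_energy <- function(reaction, conditions, species_tab) {
  dG0_T <- standard_gibbs(reaction, species_tab, conditions$temperature)
  lnQ <- reaction_quotient(reaction, conditions, species_tab)
  dG <- dG0_T + .R_KJ * conditions$temperature * lnQ
  structure(
    list(reaction_id = reaction$id, donor = reaction$donor,
         n_electrons = reaction$n_electrons,
         temperature_K = conditions$temperature,
         dG0_T = dG0_T, lnQ = lnQ, dG = dG,
         dG_per_electron = dG / reaction$n_electrons),
    class = "energy_result")
}

#' @export
print.energy_result <- function(x, ...) {
  cat(sprintf(
    "<energy_result %s> T = %.2f K\n  dG0(T) = %.3f kJ/mol, lnQ = %.3f\n  dG = %.3f kJ/mol, per electron = %.3f kJ/(mol e-)\n",
    x$reaction_id, x$temperature_K, x$dG0_T, x$lnQ, x$dG,
    x$dG_per_electron))
  invisible(x)
}

#' Sweep the electron-donor concentration
#'
#' Re-evaluates the in situ energy yield with the donor molality
#' overridden to each grid value, all other conditions fixed. Because only
#' the donor's activity term changes, the per-electron yield decreases
#' (becomes more negative) as donor concentration rises.
#'
#' @inheritParams reaction_quotient
#' @param grid Strictly positive, strictly increasing donor molalities.
#' @return Data frame with columns `reaction_id`, `donor`,
#'   `donor_molality`, `dG0_T`, `lnQ`, `dG`, `dG_per_electron`.
#' @examples
#' sp <- species_table()
#' rx <- shipped_reactions()
#' sweep_donor(rx$co_sulfate, fluid_profile("jdfr"),
#'             c(1e-8, 1e-6, 1e-4), sp)
#' @export
sweep_donor <- function(reaction, conditions, grid, species_tab) {
  if (length(grid) == 0L) stop("donor grid is empty")
  if (any(grid <= 0)) stop("donor grid must be strictly positive")
  if (length(grid) > 1L && any(diff(grid) <= 0)) {
    stop("donor grid must be strictly increasing")
  }
  rows <- lapply(grid, function(m) {
    conc <- conditions$concentrations
    conc[reaction$donor] <- m
    cond_m <- fluid_conditions(conditions$temperature, conc, conditions$pH,
                               conditions$ionic_strength,
                               conditions$activity_model,
                               name = conditions$name)
    e <- gibbs_energy(reaction, cond_m, species_tab)
    data.frame(reaction_id = e$reaction_id, donor = e$donor,
               donor_molality = m, dG0_T = e$dG0_T, lnQ = e$lnQ,
               dG = e$dG, dG_per_electron = e$dG_per_electron,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rank electron donors by per-electron energy yield
#'
#' Evaluates each reaction with its donor set to a common (matched)
#' molality and orders the results by `dG_per_electron`, most exergonic
#' (most negative) first; ties break lexicographically by reaction id.
#'
#' @param reactions List of `reaction` objects.
#' @inheritParams reaction_quotient
#' @param donor_concentration Molality applied to every reaction's donor.
#' @return Data frame `reaction_id`, `donor`, `dG_per_electron`, ordered.
#' @examples
#' sp <- species_table()
#' rank_donors(shipped_reactions(), fluid_profile("jdfr"), 1e-6, sp)
#' @export
rank_donors <- function(reactions, conditions, donor_concentration,
                        species_tab) {
  stopifnot(length(reactions) > 0, donor_concentration > 0)
  rows <- lapply(reactions, function(rx) {
    conc <- conditions$concentrations
    conc[rx$donor] <- donor_concentration
    cond <- fluid_conditions(conditions$temperature, conc, conditions$pH,
                             conditions$ionic_strength,
                             conditions$activity_model,
                             name = conditions$name)
    e <- gibbs_energy(rx, cond, species_tab)
    data.frame(reaction_id = e$reaction_id, donor = e$donor,
               dG_per_electron = e$dG_per_electron,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$dG_per_electron, out$reaction_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
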