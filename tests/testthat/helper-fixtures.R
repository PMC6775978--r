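# Shared fixtures and independent brute-force oracles.
# Oracles are deliberately written as plain loops, independent of the
# package's vectorized implementations.

# --- toy species table -------------------------------------------------

toy_species_file <- function(dGf = c(A = 0, B = -10),
                             dHf = c(A = 0, B = 0),
                             charge = c(A = 0, B = 0)) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  lines <- c("name\tformula\tcharge\tphase\tdGf0_kJ_mol\tdHf0_kJ_mol\tsource")
  for (nm in names(dGf)) {
    lines <- c(lines, sprintf("%s\tX1\t%d\taqueous\t%g\t%g\ttoy",
                              nm, charge[[nm]], dGf[[nm]], dHf[[nm]]))
  }
  writeLines(lines, path)
  path
}

toy_reaction <- function(id = "toy", stoich = c(A = -1, B = 1),
                         n_electrons = 1) {
  reaction(id, stoich, n_electrons, donor = "A", acceptor = "A")
}

# conditions with every listed activity at 1 (pH 0 so a(H+) = 1)
unit_conditions <- function(species_names, temperature = 298.15) {
  conc <- stats::setNames(rep(1, length(species_names)), species_names)
  fluid_conditions(temperature, conc, pH = 0, ionic_strength = 0,
                   activity_model = "ideal")
}

# --- brute-force oracles -----------------------------------------------

oracle_standard_gibbs <- function(rx, sp, temperature) {
  dG0 <- 0
  dH0 <- 0
  for (nm in names(rx$stoichiometry)) {
    nu <- rx$stoichiometry[[nm]]
    dG0 <- dG0 + nu * sp[nm, "dGf0_kJ_mol"]
    dH0 <- dH0 + nu * sp[nm, "dHf0_kJ_mol"]
  }
  (temperature / 298.15) * dG0 + (1 - temperature / 298.15) * dH0
}

oracle_lnq <- function(rx, sp, cond) {
  total <- 0
  for (nm in names(rx$stoichiometry)) {
    nu <- rx$stoichiometry[[nm]]
    if (sp[nm, "phase"] == "liquid-water") {
      a <- 1
    } else if (nm == "H+") {
      a <- 10^(-cond$pH)
    } else {
      g <- activity_coefficient(sp[nm, "charge"], cond$ionic_strength,
                                cond$temperature, cond$activity_model)
      a <- g * cond$concentrations[[nm]]
    }
    total <- total + nu * log(a)
  }
  total
}

# N50 as the largest length L present such that contigs >= L hold at
# least half the bases (scan over unique lengths, largest first).
oracle_n50 <- function(lengths) {
  half <- sum(lengths) / 2
  for (L in sort(unique(lengths), decreasing = TRUE)) {
    if (sum(lengths[lengths >= L]) >= half) return(L)
  }
  stop("unreachable")
}

# annotation fixture: one genome carrying the given gene symbols
annotations_with_symbols <- function(genome_id, symbols) {
  if (length(symbols) == 0L) {
    return(data.frame(genome_id = character(), gene_id = character(),
                      cog_id = character(), cog_category = character(),
                      ko_id = character(), symbol = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(genome_id = genome_id,
             gene_id = sprintf("%s_%03d", genome_id, seq_along(symbols)),
             cog_id = NA_character_, cog_category = NA_character_,
             ko_id = NA_character_, symbol = symbols,
             stringsAsFactors = FALSE)
}

glycolysis_members <- function(sets = marker_sets()) {
  sets$member[sets$set_name == "glycolysis"]
}
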