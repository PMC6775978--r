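test_that("motility relative abundance is counts[N] / total", {
  p <- genome_profile("s1", "metagenome", "sediment",
                      counts = c(N = 5, C = 95), total_annotated = 100)
  expect_equal(motility_relative_abundance(p), 0.05)
  p0 <- genome_profile("s2", "metagenome", "sediment",
                       counts = c(C = 100), total_annotated = 100)
  expect_equal(motility_relative_abundance(p0), 0)
  pz <- genome_profile("s3", "metagenome", "sediment",
                       counts = integer(), total_annotated = 0)
  expect_error(motility_relative_abundance(pz), "no annotated genes")
})

test_that("profiles tally category letters, multi-letter strings included", {
  ann <- data.frame(
    genome_id = "g1", gene_id = sprintf("g%02d", 1:11),
    cog_id = NA_character_,
    cog_category = c(rep("N", 3), rep("C", 7), "NT"),
    ko_id = NA_character_, symbol = NA_character_,
    stringsAsFactors = FALSE)
  p <- profile_from_annotations(
    ann, list(sample_id = "g1", sample_type = "genome",
              environment = "crustal_aquifer", completeness = 50))
  expect_equal(p$total_annotated, 11)
  expect_equal(unname(p$counts["N"]), 4L)
  expect_equal(unname(p$counts["T"]), 1L)
  expect_equal(unname(p$counts["C"]), 7L)
  # genes without a category don't enter the denominator
  ann2 <- rbind(ann, data.frame(genome_id = "g1", gene_id = "g12",
                                cog_id = NA, cog_category = NA,
                                ko_id = NA, symbol = "dsrA"))
  p2 <- profile_from_annotations(
    ann2, list(sample_id = "g1", sample_type = "genome",
               environment = "crustal_aquifer", completeness = 50))
  expect_equal(p2$total_annotated, 11)
})

test_that("profile metadata must be complete", {
  ann <- annotations_with_symbols("g1", "sat")
  expect_error(profile_from_annotations(
    ann, list(sample_id = "g1", sample_type = "genome")),
    "environment")
  expect_error(profile_from_annotations(
    ann, list(sample_id = "g1", sample_type = "genome",
              environment = "sediment")),
    "completeness")
})

test_that("profile from generated annotations equals a brute-force count", {
  sim <- gen_annotations(sim_spec(seed = 7,
                                  n_genomes = c(crustal_aquifer = 2)))
  for (gid in unique(sim$metadata$sample_id)) {
    p <- profile_from_annotations(sim$annotations,
                                  sim$metadata[sim$metadata$sample_id == gid, ])
    # independent pass over the raw table
    rows <- sim$annotations[sim$annotations$genome_id == gid, ]
    n_N <- 0
    n_tot <- 0
    for (i in seq_len(nrow(rows))) {
      cc <- rows$cog_category[i]
      if (!is.na(cc) && nzchar(cc)) {
        n_tot <- n_tot + 1
        if (grepl("N", cc, fixed = TRUE)) n_N <- n_N + 1
      }
    }
    expect_equal(motility_relative_abundance(p), n_N / n_tot)
  }
})

test_that("completeness filter is inclusive and spares metagenomes", {
  mk <- function(id, type, comp) {
    genome_profile(id, type, "sediment", counts = c(N = 1, C = 9),
                   total_annotated = 10, completeness = comp)
  }
  profiles <- list(mk("a", "genome", 9.9), mk("b", "genome", 10.0),
                   mk("c", "genome", 55), mk("d", "metagenome", NA))
  kept <- filter_by_completeness(profiles, 10)
  expect_identical(vapply(kept, `[[`, "", "sample_id"), c("b", "c", "d"))
  expect_length(filter_by_completeness(profiles, 0), 4L)
})

test_that("group quartiles use the inclusive-median (Tukey hinge) method", {
  mk <- function(id, env, n_motile) {
    genome_profile(id, "metagenome", env,
                   counts = c(N = n_motile, C = 100 - n_motile),
                   total_annotated = 100)
  }
  profiles <- list(mk("a", "sediment", 1), mk("b", "sediment", 2),
                   mk("c", "sediment", 3), mk("d", "sediment", 4))
  gs <- group_quartiles(profiles)
  expect_equal(gs$q1, 0.015)
  expect_equal(gs$median, 0.025)
  expect_equal(gs$q3, 0.035)
  # one sample: all five numbers coincide
  gs1 <- group_quartiles(list(mk("x", "water_column", 2)))
  expect_true(all(gs1[c("min", "q1", "median", "q3", "max")] == 0.02))
  # groups are environment-sorted
  gs2 <- group_quartiles(list(mk("x", "water_column", 2),
                              mk("y", "crustal_aquifer", 3)))
  expect_identical(gs2$environment, c("crustal_aquifer", "water_column"))
  expect_identical(nrow(group_quartiles(list())), 0L)
})

test_that("duplicating every gene record leaves the abundance unchanged", {
  ann <- data.frame(
    genome_id = "g1", gene_id = sprintf("g%02d", 1:10),
    cog_id = NA_character_,
    cog_category = c(rep("N", 2), rep("C", 8)),
    ko_id = NA_character_, symbol = NA_character_,
    stringsAsFactors = FALSE)
  doubled <- rbind(ann, transform(ann, gene_id = paste0(gene_id, "_dup")))
  md <- list(sample_id = "g1", sample_type = "metagenome",
             environment = "sediment", completeness = NA)
  expect_equal(
    motility_relative_abundance(profile_from_annotations(ann, md)),
    motility_relative_abundance(profile_from_annotations(doubled, md)))
})

test_that("motility table reports the experimental per-completeness column", {
  p <- genome_profile("g", "genome", "crustal_aquifer",
                      counts = c(N = 3, C = 97), total_annotated = 100,
                      completeness = 50)
  tab <- motility_table(list(p))
  expect_equal(tab$rel_abundance, 0.03)
  expect_equal(tab$rel_abundance_per_completeness, 0.06)
})
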