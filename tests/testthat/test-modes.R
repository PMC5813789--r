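# Orchestration: analysis / synthesis / combination, filtering and pruning
# variants, batch exclusion and the keyword file.

campaign_files <- function(cfg) {
  camp <- simulate_campaign(cfg)
  dir <- tempfile("camp")
  write_campaign(camp, dir)
  list(camp = camp, dir = dir,
       files = readLines(file.path(dir, "filelist.txt")))
}

test_that("analysis mode renumbers, summarizes and serializes", {
  cf <- campaign_files(small_config(201, datasets_per_group = 5))
  out <- tempfile("ws")
  an <- analysis_mode(cf$files, outdir = out)
  expect_equal(unname(vapply(an$datasets, `[[`, integer(1), "id")), 1:5)
  expect_equal(nrow(an$cluster_table), 4)
  expect_equal(nrow(an$sweeps), 5)
  expect_true(all(file.exists(file.path(out,
    c("final_list_of_files.tsv", "dendrogram.nwk", "dendrogram.txt",
      "clusters.json")))))
  # a corrupt file aborts full analysis naming it, is skipped in
  # dendrogram-only mode
  bad <- file.path(cf$dir, "corrupt.uxt")
  writeLines("not a dataset", bad)
  expect_error(analysis_mode(c(cf$files, bad)), "corrupt.uxt")
  expect_warning(an2 <- analysis_mode(c(cf$files, bad),
                                      dendrogram_only = TRUE),
                 "corrupt.uxt")
  expect_length(an2$datasets, 5)
  expect_null(an2$sweeps)
  # dendrogram-only yields the identical tree on clean input
  an3 <- analysis_mode(cf$files, dendrogram_only = TRUE)
  expect_identical(as_newick(an3$dendrogram), as_newick(an$dendrogram))
})

test_that("synthesis of a cluster equals combination of its members", {
  cf <- campaign_files(small_config(211, n_groups = 2,
                                    datasets_per_group = 3))
  an <- analysis_mode(cf$files)
  ct <- an$cluster_table
  for (cl in c(1, nrow(ct))) {
    members <- as.integer(cluster_members(ct, cl))
    if (length(members) < 2) next
    s1 <- synthesis_mode(an, cl, resolution_max = 6.5)
    s2 <- combination_mode(an, members, resolution_max = 6.5)
    expect_equal(s1$overall, s2$overall)
    # permutation invariance of the serial list
    s3 <- combination_mode(an, rev(members), resolution_max = 6.5)
    expect_equal(s2$overall, s3$overall)
  }
  expect_error(synthesis_mode(an, 99), "1..")
  expect_error(combination_mode(an, integer(0)), "empty")
  expect_error(combination_mode(an, 42), "serial")
  # singleton list: statistics of that dataset alone
  solo <- combination_mode(an, 2)
  direct <- compute_stats(list(an$datasets[[2]]))
  expect_equal(solo$overall, direct$overall)
})

test_that("batch exclusion drops ranges and composes with merging", {
  cf <- campaign_files(small_config(221, datasets_per_group = 3))
  an <- analysis_mode(cf$files)
  ds <- an$datasets
  expect_identical(apply_batch_exclusions(ds, list()), ds)
  # exclusion then merge equals merge of a pre-trimmed copy
  ex <- list(`2` = list(c(6, 10)))
  st1 <- combination_mode(an, 1:3, batch_exclusions = ex)
  trimmed <- ds
  ob <- ds[[2]]$observations
  trimmed[[2]] <- new_dataset(ob[ob$batch < 6, ], ds[[2]]$cell,
                              ds[[2]]$space_group, label = ds[[2]]$label,
                              id = ds[[2]]$id)
  st2 <- compute_stats(trimmed, fit_scales(trimmed))
  expect_equal(st1$overall, st2$overall)
  # excluding every batch drops the dataset with a warning
  expect_warning(left <- apply_batch_exclusions(ds, list(`3` = c(1, 10))),
                 "no observations left")
  expect_length(left, 2)
  expect_error(apply_batch_exclusions(ds, list(`1` = c(7, 3))),
               "first <= last")
})

test_that("filtering discards exactly a planted bad dataset", {
  # good datasets of homogeneous quality (equal true scale and B), so the
  # planted perturbation is the only genuine quality difference
  cf <- campaign_files(small_config(231, datasets_per_group = 5,
                                    coverage = 0.4,
                                    scale_range = c(1, 1),
                                    b_range = c(0, 0)))
  an <- analysis_mode(cf$files)
  an$datasets[[3]] <- spoil_dataset(an$datasets[[3]], seed = 3)
  res <- filtering_variant(an, 1:5, completeness_threshold = 90,
                           resolution_max = 6.5)
  expect_equal(res$removed_serials, 3L)
  expect_setequal(res$final_serials, c(1, 2, 4, 5))
  expect_lt(res$stats_final$overall$rmeas, res$stats_initial$overall$rmeas)
  expect_gte(res$stats_final$overall$completeness, 90)
  # exhaustive oracle: of all single removals, dropping 3 minimizes Rmeas
  singles <- vapply(1:5, function(s)
    combination_mode(an, setdiff(1:5, s),
                     resolution_max = 6.5)$overall$rmeas, numeric(1))
  expect_equal(which.min(singles), 3L)
  expect_equal(res$stats_final$overall$rmeas, min(singles))
  # audit trail records every trial of every round
  expect_gte(length(res$audit), 1)
  expect_equal(sort(res$audit[[1]]$trials$serial), 1:5)
  expect_equal(res$audit[[1]]$committed, 3L)
  # committed Rmeas strictly decreases across rounds
  committed <- Filter(function(a) !is.null(a$committed), res$audit)
  expect_length(committed, 1)
})

test_that("filtering is a no-op on identical copies and respects floors", {
  base <- simulate_campaign(small_config(241,
                                         datasets_per_group = 1))$datasets[[1]]
  copies <- lapply(1:4, function(i)
    new_dataset(base$observations, base$cell, base$space_group,
                label = paste0("c", i), id = i))
  res <- filtering_variant(copies, 1:4, completeness_threshold = 50)
  expect_length(res$removed_serials, 0)
  expect_equal(res$stats_final$overall, res$stats_initial$overall)
  expect_error(filtering_variant(copies, 1:4, completeness_threshold = 0),
               "0, 100")
  expect_error(filtering_variant(copies, 1), "at least 2")
})

test_that("filtered supersets converging to one member set agree exactly", {
  cf <- campaign_files(small_config(251, datasets_per_group = 6,
                                    coverage = 0.4,
                                    scale_range = c(1, 1),
                                    b_range = c(0, 0)))
  an <- analysis_mode(cf$files)
  an$datasets[[5]] <- spoil_dataset(an$datasets[[5]], seed = 5)
  an$datasets[[6]] <- spoil_dataset(an$datasets[[6]], seed = 6, factor = 6)
  r1 <- filtering_variant(an, c(1, 2, 3, 4, 5), 90, resolution_max = 6.5)
  r2 <- filtering_variant(an, c(1, 2, 3, 4, 5, 6), 90,
                          resolution_max = 6.5)
  expect_setequal(r1$final_serials, c(1, 2, 3, 4))
  expect_setequal(r2$final_serials, c(1, 2, 3, 4))
  expect_equal(r1$stats_final$overall, r2$stats_final$overall)
})

test_that("pruning removes a damaged tail and nothing otherwise", {
  # no damage: stats unchanged, nothing pruned
  cf0 <- campaign_files(small_config(261, datasets_per_group = 3,
                                     coverage = 0.4))
  an0 <- analysis_mode(cf0$files)
  r0 <- pruning_variant(an0, 1:3, completeness_threshold = 90, chunk = 5,
                        resolution_max = 6.5)
  expect_length(r0$removed_batches, 0)
  expect_equal(r0$stats_final$overall, r0$stats_initial$overall)
  # planted damage on dataset 2's tail
  cfg <- small_config(263, datasets_per_group = 3, coverage = 0.4,
                      beta = 3, delta = 0.3, damage_datasets = 2)
  cf <- campaign_files(cfg)
  an <- analysis_mode(cf$files)
  r <- pruning_variant(an, 1:3, completeness_threshold = 90, chunk = 5,
                       resolution_max = 6.5)
  expect_true("2" %in% names(r$removed_batches))
  expect_equal(r$removed_batches[["2"]][[1]], c(6, 10))
  expect_lt(r$stats_final$overall$rmeas, r$stats_initial$overall$rmeas)
  expect_gte(r$stats_final$overall$completeness, 90)
  # exhaustive single-chunk oracle: pruning dataset 2's tail is the best
  # (and an improving) first move
  trial_rmeas <- vapply(1:3, function(s) {
    ex <- list(); ex[[as.character(s)]] <- list(c(6, 10))
    combination_mode(an, 1:3, resolution_max = 6.5,
                     batch_exclusions = ex)$overall$rmeas
  }, numeric(1))
  expect_equal(which.min(trial_rmeas), 2L)
  expect_lt(trial_rmeas[2], r$stats_initial$overall$rmeas)
  # replay reproduces the final statistics bit for bit
  expect_equal(replay_combination(an, r)$overall, r$stats_final$overall)
})

test_that("keyword files parse all directives with CLI-style precedence", {
  kw <- tempfile()
  writeLines(c("RESO HIGH 3.5", "batch exclude 2 6 10",
               "BATCH EXCLUDE 2 1 1", "completeness 97", "CHUNK 3",
               "# comment"), kw)
  parsed <- read_keywords(kw)
  expect_equal(parsed$resolution_max, 3.5)
  expect_equal(parsed$completeness, 97)
  expect_equal(parsed$chunk, 3)
  expect_equal(parsed$batch_exclusions[["2"]],
               list(c(6, 10), c(1, 1)))
  writeLines("BATCH EXCLUDE 2 9 4", kw)
  expect_error(read_keywords(kw), "malformed")
  writeLines("FROBNICATE 1", kw)
  expect_error(read_keywords(kw), "unknown keyword")
})
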