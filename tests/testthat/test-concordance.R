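# scoring GMYC species against user-predefined groups

test_that("fixture species are classified into all five categories", {
  fx <- figure1_fixture()
  cls <- classify_species(fx$imposed_partition, fx$truth$groups)
  got <- stats::setNames(cls$category, cls$groups_present)
  expect_equal(unname(got[["sp1,sp2,sp3"]]), "merge_I")
  expect_equal(unname(got[["spW,spY"]]), "merge_II")
  expect_equal(unname(got[["spZ"]]), "exact")
  expect_equal(sum(cls$category == "split" & cls$groups_present == "spA"), 2L)
  expect_equal(unname(got[["spB"]]), "singleton")
  expect_equal(cls$match_flag[cls$category %in% c("split", "exact")],
               rep("y", 3))
  expect_equal(cls$match_flag[cls$category %in% c("merge_I", "merge_II")],
               rep("n", 2))
})

test_that("degenerate classifications: perfect match and all singletons", {
  samples <- sprintf("s%02d", 1:12)
  gm <- group_map(samples, rep(c("gA", "gB", "gC"), each = 4))
  perfect <- species_partition(split(samples, rep(1:3, each = 4)))
  cls <- classify_species(perfect, gm)
  expect_true(all(cls$category == "exact"))

  allsing <- species_partition(as.list(samples))
  cls2 <- classify_species(allsing, gm)
  expect_true(all(cls2$category == "singleton"))

  # a singleton species matching a 1-sample user group stays a singleton
  gm3 <- group_map(c("a", "b", "c"), c("g1", "g1", "g2"))
  part3 <- species_partition(list(c("a", "b"), "c"))
  cls3 <- classify_species(part3, gm3)
  expect_equal(sort(cls3$category), c("exact", "singleton"))

  expect_error(classify_species(perfect, gm[1:6]),
               class = "crosscheck_error")
})

test_that("percentage match, splitting ratio and singleton percentage", {
  expect_equal(percentage_match(3, 2, 1, TRUE), 100 * 4 / 6)
  expect_equal(round_half_up(percentage_match(3, 2, 1, TRUE)), 67)
  expect_equal(percentage_match(3, 2, 1, FALSE), 60)
  expect_equal(percentage_match(5, 0, 0, TRUE), 100)
  expect_equal(percentage_match(5, 0, 0, FALSE), 100)
  expect_warning(out <- percentage_match(0, 0, 3, FALSE))
  expect_true(is.na(out))

  expect_equal(splitting_ratio(6, 1, 8, TRUE), 0.75)
  expect_equal(splitting_ratio(6, 1, 8, FALSE), 0.625)
  expect_equal(round_half_up(splitting_ratio(6, 1, 8, FALSE), 2), 0.63)
  expect_equal(splitting_ratio(8, 0, 8, TRUE), 1)
  expect_equal(splitting_ratio(8, 0, 8, FALSE), 1)

  expect_equal(singleton_percentage(1, 6), 100 / 6)
  expect_equal(round_half_up(singleton_percentage(1, 6)), 17)
  expect_equal(singleton_percentage(0, 9), 0)
  expect_equal(singleton_percentage(4, 4), 100)
})

test_that("per-group split factors count containing species", {
  fx <- figure1_fixture()
  fac <- per_group_split_factor(fx$imposed_partition, fx$truth$groups)
  expect_equal(unname(fac[["spA"]]), 2L)
  expect_equal(unname(fac[["spZ"]]), 1L)
  expect_equal(unname(fac[["sp1"]]), 1L)

  # group of 3 split 2 + 1: factor 2 including singleton species, 1 without
  gm <- group_map(c("a", "b", "c", "d", "e"), c("g", "g", "g", "h", "h"))
  part <- species_partition(list(c("a", "b"), "c", c("d", "e")))
  fac2 <- per_group_split_factor(part, gm)
  expect_equal(unname(fac2[["g"]]), 2L)
  fac3 <- per_group_split_factor(part, gm, include_singleton_species = FALSE)
  expect_equal(unname(fac3[["g"]]), 1L)
})

test_that("run_metrics reproduces the full worked example", {
  fx <- figure1_fixture()
  rm_ <- run_metrics(fx$imposed_partition, fx$truth$groups)
  expect_equal(rm_$y_count, 3L)
  expect_equal(rm_$n_count, 2L)
  expect_equal(rm_$singleton_count, 1L)
  expect_equal(round_half_up(rm_$m_incl), 67)
  expect_equal(round_half_up(rm_$m_excl), 60)
  expect_equal(round_half_up(rm_$m_incl - rm_$m_excl), 7)
  expect_equal(rm_$exact_groups, "spZ")
  expect_equal(rm_$exact_match_incidence, 12.5)
  expect_equal(round_half_up(rm_$exact_match_incidence), 13)
  expect_equal(nrow(rm_$merges), 2L)
  expect_setequal(rm_$merges$merge_type, c("merge_I", "merge_II"))
  # match table: one row per sample, flags constant within a species
  expect_equal(nrow(rm_$match_table), 16L)
  flags <- tapply(rm_$match_table$match, rm_$match_table$gmyc_species_id,
                  function(v) length(unique(v)))
  expect_true(all(flags == 1L))

  # identical partition and groups: all exact, ratios 1
  samples <- sprintf("s%02d", 1:12)
  gm <- group_map(samples, rep(c("gA", "gB", "gC"), each = 4))
  perfect <- species_partition(split(samples, rep(1:3, each = 4)))
  rp <- run_metrics(perfect, gm)
  expect_equal(rp$m_incl, 100)
  expect_equal(rp$m_excl, 100)
  expect_equal(rp$sr_incl, 1)
  expect_equal(rp$exact_match_incidence, 100)
  expect_equal(nrow(rp$merges), 0L)
})

test_that("exact match scores average across runs", {
  fx <- figure1_fixture()
  rm1 <- run_metrics(fx$imposed_partition, fx$truth$groups) # spZ exact
  # a run where nothing is exact: one big species
  all_in_one <- species_partition(list(fx$truth$tree$tip.label))
  rm0 <- run_metrics(all_in_one, fx$truth$groups)
  sc <- exact_match_scores(list(rm1, rm1, rm0),
                           all_groups = group_labels(fx$truth$groups))
  expect_equal(unname(sc[["spZ"]]), 100 * 2 / 3)
  expect_equal(round_half_up(sc[["spZ"]]), 67)
  expect_equal(unname(sc[["spA"]]), 0)
  sc3 <- exact_match_scores(list(rm1, rm1, rm1))
  expect_equal(unname(sc3[["spZ"]]), 100)
})

test_that("classification is invariant to species and sample order", {
  fx <- figure1_fixture()
  part <- fx$imposed_partition
  shuffled <- species_partition(lapply(rev(unclass(part)), rev))
  expect_identical(classify_species(part, fx$truth$groups),
                   classify_species(shuffled, fx$truth$groups))
})

test_that("metric algebra invariants hold on random partitions", {
  for (seed in 1:200) {
    pg <- random_partition_and_groups(5 + seed %% 20, seed)
    rm_ <- suppressWarnings(run_metrics(pg$partition, pg$groups))
    expect_equal(rm_$y_count + rm_$n_count + rm_$singleton_count,
                 length(pg$partition))
    if (!is.na(rm_$m_excl)) expect_gte(rm_$m_incl, rm_$m_excl - 1e-12)
    expect_equal(rm_$sr_incl - rm_$sr_excl,
                 rm_$singleton_count / rm_$n_groups, tolerance = 1e-12)
    cnt <- entity_counts(pg$partition)
    expect_equal(cnt[["singletons"]], rm_$singleton_count)
    expect_equal(cnt[["entities"]], rm_$n_species)
  }
})
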