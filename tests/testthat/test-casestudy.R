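test_that("case-study bundles save and load with bit-exact layers and tables", {
  withr::with_seed(4, {
    cs <- local_case_study(seed = 4)
    dir <- withr::local_tempdir()
    save_case_study(cs, dir, overwrite = TRUE)
    cs2 <- load_case_study(dir)
    expect_identical(lapply(cs2$uses, `[[`, "values"),
                     lapply(cs$uses, `[[`, "values"))
    expect_identical(lapply(cs2$envs, `[[`, "values"),
                     lapply(cs$envs, `[[`, "values"))
    expect_identical(cs2$links, cs$links)
    expect_identical(cs2$sensitivities, cs$sensitivities)
    expect_identical(cs2$use_attributes, cs$use_attributes)
    expect_identical(cs2$grid, cs$grid)
    expect_identical(cs2$title, cs$title)
  })
})

test_that("the shipped demo case loads and runs both models end to end", {
  demo <- system.file("extdata", "demo_case", package = "mspgrid")
  expect_true(nzchar(demo))
  cs <- load_case_study(demo)
  expect_gte(length(cs$uses), 2L)
  expect_gte(length(cs$envs), 1L)
  rep <- validate_case_study(cs)
  expect_length(rep$errors, 0L)
  muc <- run_muc(cs)
  cea <- run_cea(cs)
  expect_s3_class(muc, "muc_result")
  expect_s3_class(cea, "cea_result")
  expect_true(all(cea$total_map$values >= 0, na.rm = TRUE))
})

test_that("loading reports missing files and dangling identifiers by name", {
  withr::with_seed(6, {
    dir <- withr::local_tempdir()
    save_case_study(local_case_study(seed = 6), dir, overwrite = TRUE)
    expect_error(load_case_study(file.path(dir, "nope")), "manifest")
    # missing referenced layer file
    man <- jsonlite::read_json(file.path(dir, "casestudy.json"))
    file.remove(file.path(dir, man$layers[[1]]$file))
    expect_error(load_case_study(dir), man$layers[[1]]$name)
  })
})

test_that("a bundle without sensitivities loads for MUC but refuses CEA", {
  withr::with_seed(8, {
    dir <- withr::local_tempdir()
    save_case_study(local_case_study(seed = 8), dir, overwrite = TRUE)
    file.remove(file.path(dir, "inputs", "sensitivities.csv"))
    cs <- load_case_study(dir)
    expect_s3_class(run_muc(cs), "muc_result")
    expect_error(run_cea(cs), "sensitivities")
  })
})

test_that("validation reports rather than throws, naming offenders", {
  cs <- local_case_study(seed = 3)
  rep <- validate_case_study(cs)
  expect_length(rep$errors, 0L)
  # dangling link use
  cs_bad <- cs
  cs_bad$links <- rbind(cs_bad$links,
                        data.frame(use = "x", pressure = cs$pressures[1],
                                   weight = 0.5, distance_m = 0))
  rep <- validate_case_study(cs_bad)
  expect_true(any(grepl("'x'", rep$errors)))
  # out-of-range weight warns, does not error
  cs_w <- cs
  cs_w$links$weight[1] <- 1.5
  rep <- validate_case_study(cs_w)
  expect_length(rep$errors, 0L)
  expect_true(any(grepl("1.5", rep$warnings)))
})

test_that("loading is order-independent in the manifest", {
  withr::with_seed(12, {
    dir <- withr::local_tempdir()
    save_case_study(local_case_study(seed = 12), dir, overwrite = TRUE)
    cs1 <- load_case_study(dir)
    man <- jsonlite::read_json(file.path(dir, "casestudy.json"),
                               simplifyVector = FALSE)
    man$layers <- rev(man$layers)
    jsonlite::write_json(man, file.path(dir, "casestudy.json"),
                         auto_unbox = TRUE, digits = NA)
    cs2 <- load_case_study(dir)
    for (nm in names(cs1$uses))
      expect_identical(cs2$uses[[nm]]$values, cs1$uses[[nm]]$values)
    for (nm in names(cs1$envs))
      expect_identical(cs2$envs[[nm]]$values, cs1$envs[[nm]]$values)
  })
})

test_that("per-layer pre-processing expressions are applied at load time", {
  withr::with_seed(14, {
    cs <- local_case_study(seed = 14)
    dir <- withr::local_tempdir()
    save_case_study(cs, dir, overwrite = TRUE)
    man <- jsonlite::read_json(file.path(dir, "casestudy.json"),
                               simplifyVector = FALSE)
    unm <- names(cs$uses)[1]
    for (i in seq_along(man$layers))
      if (man$layers[[i]]$name == unm)
        man$layers[[i]]$expression <- sprintf("%s * 2", unm)
    jsonlite::write_json(man, file.path(dir, "casestudy.json"),
                         auto_unbox = TRUE, digits = NA)
    cs2 <- load_case_study(dir)
    expect_equal(cs2$uses[[unm]]$values, 2 * cs$uses[[unm]]$values)
  })
})

test_that("subsetting restricts registries and filters tables consistently", {
  cs <- local_case_study(seed = 5)
  u <- names(cs$uses)[1]; e <- names(cs$envs)[1]; p <- cs$pressures[1]
  sub <- subset_case_study(cs, uses = u, envs = e, pressures = p)
  expect_equal(names(sub$uses), u)
  expect_equal(names(sub$envs), e)
  expect_equal(sub$pressures, p)
  expect_true(all(sub$links$use == u & sub$links$pressure == p))
  expect_true(all(sub$sensitivities$pressure == p &
                    sub$sensitivities$env == e))
  expect_error(subset_case_study(cs, uses = "nope"), "nope")
  # identity subset reproduces the original outputs
  full <- subset_case_study(cs, subregion = rect_polygon(-1, -1, 10001,
                                                         10001))
  expect_equal(run_cea(full)$total_map$values, run_cea(cs)$total_map$values)
  # empty area is an error
  expect_error(subset_case_study(cs, subregion = rect_polygon(20000, 20000,
                                                              30000, 30000)),
               "subregion")
})

test_that("subset of zero uses yields an all-zero MUC map", {
  cs <- local_case_study(seed = 9)
  sub <- subset_case_study(cs, uses = character(0))
  res <- run_muc(sub)
  expect_true(all(res$score_map$values[sub$grid$area_mask] == 0))
  expect_equal(nrow(res$pair_contributions), 0L)
})

test_that("dropping pressures or receptors never increases the CEA map", {
  cs <- local_case_study(seed = 10)
  full <- run_cea(cs)
  sub <- subset_case_study(cs, pressures = cs$pressures[1],
                           envs = names(cs$envs)[1])
  part <- run_cea(sub)
  expect_true(all(part$total_map$values <= full$total_map$values + 1e-9,
                  na.rm = TRUE))
})

test_that("chained subsets equal one combined subset", {
  cs <- local_case_study(seed = 11)
  a <- subset_case_study(subset_case_study(cs, uses = names(cs$uses)[1:2]),
                         envs = names(cs$envs)[1])
  b <- subset_case_study(cs, uses = names(cs$uses)[1:2],
                         envs = names(cs$envs)[1])
  expect_identical(names(a$uses), names(b$uses))
  expect_identical(names(a$envs), names(b$envs))
  expect_identical(a$links, b$links)
  expect_identical(a$sensitivities, b$sensitivities)
  r1 <- subset_case_study(cs, subregion = rect_polygon(0, 0, 6000, 10000))
  r2 <- subset_case_study(r1, subregion = rect_polygon(0, 0, 10000, 6000))
  r12 <- subset_case_study(cs, subregion = rect_polygon(0, 0, 6000, 6000))
  expect_identical(r2$grid$area_mask, r12$grid$area_mask)
})

test_that("runs delegate to the model modules and are deterministic", {
  cs <- local_case_study(seed = 2)
  res <- run_muc(cs)
  direct <- muc_map(presence_layers(cs$uses),
                    conflict_matrix(cs$use_attributes), cs$grid)
  expect_equal(res$score_map$values, direct$score_map$values)
  expect_identical(run_muc(cs)$score_map$values, res$score_map$values)
  cea1 <- run_cea(cs); cea2 <- run_cea(cs)
  expect_identical(cea1$total_map$values, cea2$total_map$values)
  expect_equal(cea1$provenance$model, "cea")
  # all-zero sensitivities give an all-zero cea map
  cs0 <- cs
  cs0$sensitivities$sensitivity <- 0
  expect_true(all(run_cea(cs0)$total_map$values == 0, na.rm = TRUE))
})
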