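test_that("the annotated params template round-trips into a buildable model", {
  f <- tempfile(fileext = ".yaml")
  make_params_file(f, n_layers = 2, n_traits = 1)
  p <- read_params(f)
  expect_length(p$landscape$layers, 2)
  expect_length(p$species$genome$traits, 1)
  p$species$genome$traits[[1]]$selection_layer <- "layer_2"
  p$landscape$layers[[2]]$roles <- list("selection")
  p$landscape$layers[[1]]$roles <- list("carrying_capacity")
  p$model$burn_in <- list(min_length = 10, lag = 5, max_length = 20)
  p$model$T <- 2
  m <- quiet_build(p, seed = 1)
  expect_s3_class(m, "gl_model")

  # defaults fill omitted values; unknown keys are rejected with location
  expect_equal(p$species$sex_ratio, 0.5)
  bad <- list(species = list(grwoth_rate = 2))
  expect_error(validate_params(bad), "species.grwoth_rate")
  writeLines(c(readLines(f), "bogus_key: 1"), f)
  expect_error(read_params(f), "bogus_key")
})

test_that("model building is deterministic and precomputes declared structures", {
  p <- tiny_params()
  p$species$genome$n_recomb_paths <- 100
  p$species$genome$L <- 50
  m1 <- quiet_build(p, seed = 9)
  m2 <- quiet_build(p, seed = 9)
  expect_identical(m1$paths$paths, m2$paths$paths)
  expect_identical(m1$pop$x, m2$pop$x)
  expect_equal(dim(m1$paths$paths), c(100L, 50L))

  # a change event on the movement layer stores one surface per scheduled
  # step plus the original
  p2 <- tiny_params()
  p2$species$movement$surface_layer <- "habitat"
  p2$species$movement$approx_len <- 20
  p2$landscape$layers[[1]]$kind <- "gradient"
  p2$landscape$layers[[1]]$roles <- list("movement", "carrying_capacity")
  p2$landscape$layers[[1]]$change <- list(
    mode = "interpolated", timesteps = as.list(c(2, 4, 6, 8, 10)),
    terminal = list(kind = "gradient", direction = "y"))
  m3 <- quiet_build(p2, seed = 1)
  expect_length(m3$move_surf$surfaces, 6)
  expect_equal(m3$move_surf$timesteps, c(0L, 2L, 4L, 6L, 8L, 10L))

  # oversize precomputation warns with a size estimate
  p3 <- tiny_params()
  p3$model$memory_warn_elements <- 10
  expect_warning(build_model(p3, seed = 1), "precomputed")
})

test_that("timestep operations apply in order with correct switches", {
  # movement off and no births: positions change only via dispersal
  # (a non-reproducing population cannot stabilise, so the burn-in cap is
  # reached by construction)
  p <- tiny_params(T = 3)
  p$species$movement$enabled <- FALSE
  p$species$b <- 0
  p$model$burn_in$max_length <- 25
  m <- suppressWarnings(run_model(quiet_build(p, seed = 2), T = 0))
  x0 <- m$pop$x; id0 <- m$pop$id
  m <- step_model(m)
  expect_equal(m$pop$x, x0[match(m$pop$id, id0)])

  # no matings: population can only shrink
  p2 <- tiny_params(T = 2)
  p2$species$b <- 0
  p2$model$burn_in$max_length <- 25
  m2 <- suppressWarnings(run_model(quiet_build(p2, seed = 3), T = 0))
  n0 <- length(m2$pop$x)
  m2 <- step_model(m2)
  expect_lte(length(m2$pop$x), n0)
  expect_equal(sum(run_log(m2, "main")$births), 0)
})

test_that("demographic change events multiply the carrying capacity", {
  sched <- dem_change_schedule(list(kind = "exponential",
                                    timesteps = as.list(c(5, 10, 15)),
                                    factor = 0.8))
  K <- matrix(2, 3, 3)
  expect_equal(apply_dem_change(K, sched, 4), K)
  expect_equal(apply_dem_change(K, sched, 5), K * 0.8)
  expect_equal(apply_dem_change(K, sched, 20), K * 0.8^3)

  cyc <- dem_change_schedule(list(kind = "cyclical",
                                  timesteps = as.list(c(2, 4, 6)),
                                  factor = 0.5))
  expect_equal(cyc$factor, c(0.5, 2, 0.5))

  expect_equal(sum(apply_dem_change(K, sched, 3)), sum(K))
  expect_error(dem_change_schedule(list(kind = "custom",
                                        timesteps = as.list(c(3, 1)),
                                        factors = as.list(c(1, 2)))),
               "increasing")
})

test_that("environmental change takes effect at the scheduled step boundary", {
  p <- tiny_params(T = 8)
  p$landscape$layers[[2]]$change <- list(
    mode = "interpolated", timesteps = as.list(c(3, 6)),
    terminal = list(kind = "uniform", value = 1))
  m <- quiet_build(p, seed = 4)
  lyr <- m$landscape$layers$env
  expect_false(identical(layer_at_time(lyr, 3), layer_at_time(lyr, 2)))
  expect_identical(layer_at_time(lyr, 3), layer_at_time(lyr, 5))
  expect_true(all(layer_at_time(lyr, 6) == 1))
})

test_that("runs are reproducible and T = 0 stops after genome assignment", {
  p <- tiny_params(T = 6, n_trait_loci = 3, selection = TRUE)
  m0 <- run_model(quiet_build(p, seed = 11), T = 0)
  expect_equal(nrow(run_log(m0, "main")), 0)
  expect_false(is.null(m0$pop$ch1))

  ma <- run_model(quiet_build(p, seed = 11))
  mb <- run_model(quiet_build(p, seed = 11))
  expect_identical(run_log(ma), run_log(mb))
  expect_identical(ma$pop$ch1, mb$pop$ch1)
  expect_identical(ma$pop$x, mb$pop$x)
})

test_that("identical seeds give byte-identical VCF, CSV, and log outputs", {
  p <- tiny_params(T = 6, n_trait_loci = 3, selection = TRUE)
  hashes <- vapply(1:2, function(i) {
    m <- run_model(quiet_build(p, seed = 21))
    d <- tempfile(); dir.create(d)
    write_vcf(m$pop$ch1, m$pop$ch2, m$pop$id, file.path(d, "out.vcf"))
    write_individuals(individuals_table(m), file.path(d, "ind.csv"), "csv")
    utils::write.csv(run_log(m), file.path(d, "log.csv"), row.names = FALSE)
    paste(tools::md5sum(file.path(d, c("out.vcf", "ind.csv", "log.csv"))),
          collapse = "")
  }, character(1))
  expect_identical(hashes[1], hashes[2])
})

test_that("extinction ends the run with a flagged status", {
  p <- tiny_params(T = 50)
  p$species$b <- 0
  p$species$max_age <- 2
  p$model$burn_in$max_length <- 25
  m <- suppressWarnings(run_model(quiet_build(p, seed = 5)))
  expect_identical(m$status, "extinct")
  expect_lt(nrow(run_log(m, "main")), 50)
  expect_equal(length(m$pop$x), 0)
})

test_that("a mid-run K reduction tracks logistic regulation", {
  ratios <- vapply(1:3, function(s) {
    p <- tiny_params(T = 120, nrows = 15, ncols = 15, K = 3)
    p$species$demographic_changes <- list(
      list(kind = "custom", timesteps = as.list(c(40, 80)),
           factors = as.list(c(0.3, 1 / 0.3))))
    m <- suppressWarnings(run_model(quiet_build(p, seed = s)))
    lg <- run_log(m, "main")
    mean(lg$N[lg$t %in% 55:80]) / mean(lg$N[lg$t %in% 10:40])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.3), 0.3 * 0.25)
})
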