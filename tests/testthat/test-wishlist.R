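test_that("the packaged gastric wish-list reproduces the published table", {
  w <- default_wishlist()
  expect_s3_class(w, "wishlist")
  expect_equal(w$prescription$dose_gy, 45)
  expect_equal(w$prescription$n_fractions, 25L)
  expect_length(w$constraints, 3)
  expect_length(w$objectives, 11)

  o1 <- w$objectives[[1]]
  expect_equal(o1$priority, 1)
  expect_equal(o1$volume, "PTV")
  expect_equal(o1$kind, "LTCP")
  expect_equal(o1$goal, 0.4)
  expect_equal(o1$params$Dp, 45)
  expect_equal(o1$params$alpha, 4)

  cons <- wishlist_table(w)
  expect_true(any(cons$block == "constraint" & cons$volume == "PTV" &
                    cons$goal == "105% of Dp"))
  expect_true(any(cons$block == "constraint" &
                    cons$volume == "PTV Shell 39 mm" &
                    cons$goal == "50% of Dp"))

  golden <- utils::read.csv(system.file("extdata",
                                        "gastric_wishlist_table.csv",
                                        package = "wishplan"),
                            stringsAsFactors = FALSE)
  golden$parameters[is.na(golden$parameters)] <- ""
  rendered <- wishlist_table(w)
  rownames(rendered) <- rownames(golden) <- NULL
  expect_equal(rendered$block, golden$block)
  expect_equal(rendered$priority, golden$priority)
  expect_equal(rendered$volume, golden$volume)
  expect_equal(rendered$type, golden$type)
  expect_equal(rendered$goal, golden$goal)
  expect_equal(rendered$parameters, golden$parameters)
})

test_that("resolve_limits converts percent limits to Gy and is idempotent", {
  w <- resolve_limits(default_wishlist())
  lims <- vapply(w$constraints, function(cn) as.numeric(cn$limit), 0)
  expect_equal(lims, c(47.25, 22.5, 47.25))
  goals <- vapply(w$objectives, function(o) as.numeric(o$goal), 0)
  expect_equal(goals[2], 40.5)   # 90% of 45
  expect_equal(goals[8], 11.25)  # 25% of 45
  w2 <- resolve_limits(w)
  expect_equal(vapply(w2$constraints, function(cn) as.numeric(cn$limit), 0),
               lims)
})

test_that("wish-lists round-trip through YAML", {
  w <- default_wishlist()
  path <- tempfile(fileext = ".yaml")
  write_wishlist(w, path)
  w2 <- load_wishlist(path)
  expect_equal(wishlist_table(w2), wishlist_table(w))
  expect_equal(w2$prescription, w$prescription)
  expect_equal(w2$relaxation, w$relaxation)
})

test_that("schema violations are rejected with the offending entry named", {
  base <- yaml::read_yaml(system.file("extdata", "gastric_wishlist.yaml",
                                      package = "wishplan"))
  bad <- base
  bad$objectives[[5]]$params$k <- NULL  # heart EUD without k
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(bad, path)
  expect_error(load_wishlist(path), "EUD needs param k")
  expect_error(load_wishlist(path), "Heart")

  bad2 <- base
  bad2$objectives[[1]]$goal <- -1
  yaml::write_yaml(bad2, path)
  expect_error(load_wishlist(path), "positive")

  bad3 <- base
  bad3$objectives[[3]]$kind <- "quantile"
  yaml::write_yaml(bad3, path)
  expect_error(load_wishlist(path), "unknown objective kind")

  expect_error(load_wishlist(tempfile()), "not found")
})
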