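test_that("well-formed files round-trip through read_visitation_table", {
  recs <- toy_records()
  f <- tempfile(fileext = ".csv")
  write.csv(recs, f, row.names = FALSE)
  got <- read_visitation_table(f)
  expect_equal(nrow(got), nrow(recs))
  expect_equal(got$visit_count, recs$visit_count)
  expect_equal(sum(got$visit_count), sum(recs$visit_count))

  # tab dialect
  ft <- tempfile(fileext = ".tsv")
  write.table(recs, ft, row.names = FALSE, sep = "\t")
  expect_equal(read_visitation_table(ft, delimiter = "\t")$visit_count,
               recs$visit_count)
})

test_that("malformed visitation input is rejected with informative errors", {
  recs <- toy_records()
  f <- tempfile(fileext = ".csv")

  bad <- recs; bad$visit_count[3] <- -1L
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_visitation_table(f), "non-negative integer.*3")

  bad <- recs; bad$visit_count <- bad$visit_count + 0.5
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_visitation_table(f), "non-negative integer")

  write.csv(recs[, -which(names(recs) == "visit_count")], f,
            row.names = FALSE)
  expect_error(read_visitation_table(f), "missing required column")

  bad <- recs; bad$flowering_quality <- 7L
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_visitation_table(f), "flowering_quality")
})

test_that("unknown labels are accepted but reported", {
  recs <- toy_records()
  recs$plant_species[1] <- "T. officinale"
  f <- tempfile(fileext = ".csv")
  write.csv(recs, f, row.names = FALSE)
  expect_message(read_visitation_table(f), "T. officinale")
})

test_that("packaged overall-totals fixture has 9 records summing to 17857", {
  f <- system.file("extdata", "overall_morphotype_totals.csv",
                   package = "pollweb")
  recs <- suppressMessages(read_visitation_table(f))
  expect_equal(nrow(recs), 9L)
  expect_equal(sum(recs$visit_count), 17857L)
  expect_setequal(recs$insect_morphotype, morphotype_labels())
})

test_that("interaction matrices cumulate counts over rounds and plots", {
  one <- data.frame(site_id = "A", landscape_context = "urban", round = 1L,
                    plot_id = "P1", spatial_config = "random",
                    plant_species = "M. inodora",
                    insect_morphotype = "Syrphidae", visit_count = 7L)
  M <- build_interaction_matrix(one, "A", "random")
  expect_s3_class(M, "interaction_matrix")
  expect_equal(M["M. inodora", "Syrphidae"], 7L)
  expect_equal(total_interactions(M), 7)

  two <- rbind(one, transform(one, round = 3L, visit_count = 2L))
  M2 <- build_interaction_matrix(two, "A", "random")
  expect_equal(M2["M. inodora", "Syrphidae"], 9L)

  expect_error(build_interaction_matrix(one, "A", "systematic"),
               "no visitation records match")
})

test_that("cumulation conserves record totals on random studies", {
  set.seed(11)
  study <- generate_study(default_presets(seed = 11))
  recs <- study$records
  webs <- build_all_networks(recs, study$sites)
  expect_equal(length(webs), 24L)

  # independent group-by-sum oracle over the raw records
  for (key in sample(names(webs), 6)) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    sel <- recs[recs$site_id == parts[1] & recs$spatial_config == parts[2], ]
    expect_equal(total_interactions(webs[[key]]), sum(sel$visit_count))
  }
  # webs partition the record set
  expect_equal(sum(vapply(webs, total_interactions, numeric(1))),
               sum(recs$visit_count))
})

test_that("build_all_networks yields one web per observed site-config pair", {
  recs <- toy_records()
  webs <- build_all_networks(recs)
  pairs <- unique(recs[, c("site_id", "spatial_config")])
  expect_equal(length(webs), nrow(pairs))

  only_sys <- recs[recs$spatial_config == "systematic" &
                     recs$site_id == "A", ]
  expect_equal(length(build_all_networks(only_sys)), 1L)

  sites <- data.frame(site_id = c("A", "B", "C"),
                      landscape_context = c("urban", "semi-natural", "urban"),
                      x = 1:3, y = 1:3)
  expect_message(build_all_networks(recs, sites), "no records for site")
})

test_that("matrix TSV round-trip is lossless and byte-stable", {
  set.seed(5)
  M <- random_web()
  M[2, ] <- 0L  # zero row must survive
  f <- tempfile(fileext = ".tsv")
  write_matrix(M, f)
  back <- read_matrix(f)
  expect_equal(unclass(back), unclass(M))
  expect_equal(attr(back, "provenance")$site_id,
               attr(M, "provenance")$site_id)
  expect_equal(attr(back, "provenance")$rounds, attr(M, "provenance")$rounds)

  f2 <- tempfile(fileext = ".tsv")
  write_matrix(M, f2)
  expect_identical(readLines(f), readLines(f2))

  # dimension/label mismatch -> format error
  lines <- readLines(f)
  writeLines(c(lines[1:5], paste0(lines[6], "\t99")), f2)
  expect_error(read_matrix(f2), "ragged")
})
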