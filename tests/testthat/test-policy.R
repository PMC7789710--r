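test_that("abo_relation reproduces the donor-to-recipient ABO matrix", {
  types <- c("O", "A", "B", "AB")
  for (donor in types) {
    for (cand in types) {
      expect_identical(abo_relation(cand, donor), oracle_abo(cand, donor),
                       info = paste(cand, "from", donor))
    }
  }
  expect_identical(abo_relation("A", "A"), "identical")
  expect_identical(abo_relation("AB", "O"), "compatible")
  expect_identical(abo_relation("O", "A"), "incompatible")
  expect_error(abo_relation("C", "A"), "blood-type")
})

test_that("zone_of maps distances to concentric zones with a closed A bound", {
  expect_identical(zone_of(c(0, 250, 251, 500, 1000.5, 1500, 2500, 2600)),
                   c("A", "A", "B", "B", "D", "D", "E", "F"))
  expect_error(zone_of(-1), "non-negative")
  set.seed(42)
  d <- runif(500, 0, 5000)
  expect_identical(zone_of(d), vapply(d, oracle_zone, character(1)))
})

test_that("default tables are valid and classify hits the documented cells", {
  adult <- adult_policy_table()
  ped <- pediatric_policy_table()
  expect_identical(nrow(adult), 36L)
  expect_silent(validate_policy_table(adult))
  expect_silent(validate_policy_table(ped))
  # adult table: zone A 12-plus identical is cell 1; zone B compatible is 8;
  # zone A under-12 identical is 4
  expect_identical(classify(45, "A", "identical", adult), 1L)
  expect_identical(classify(45, "B", "compatible", adult), 8L)
  expect_identical(classify(7, "A", "identical", adult), 4L)
  # pediatric: proximal children come first, adolescents precede adults
  expect_lt(classify(7, "C", "incompatible", ped),
            classify(15, "A", "identical", ped))
  expect_lt(classify(15, "B", "identical", ped),
            classify(40, "B", "identical", ped))
  expect_error(classify(45, "A", "identical", adult[-1, ]),
               "A\\|adolescent\\|identical|does not cover")
  expect_error(validate_policy_table(rbind(adult, adult[1, ])), "duplicat")
})

test_that("run_match ranks the zone-boundary worked example as policy does", {
  pool <- data.frame(id = c("A", "B"), age_years = 45, las = c(50, 90),
                     waiting_time_days = 100, abo = "O",
                     center_x = c(200, 251), center_y = 0,
                     stringsAsFactors = FALSE)
  donor <- list(id = "D1", age_years = 50, abo = "O",
                hospital_x = 0, hospital_y = 0)
  run <- run_match(donor, pool)
  # the LAS 50 candidate in zone A is offered the lungs before the much more
  # medically urgent LAS 90 candidate at 251 NM
  expect_identical(run$entries$candidate_id, c("A", "B"))
  expect_identical(run$entries$policy_rank, 1:2)
  expect_identical(run$entries$zone, c("A", "B"))
})

test_that("within a classification cell adults sort by descending LAS", {
  pool <- data.frame(id = c("lo", "hi"), age_years = 30, las = c(40, 60),
                     waiting_time_days = 10, abo = "A",
                     center_x = c(100, 120), center_y = 0,
                     stringsAsFactors = FALSE)
  donor <- list(id = "D", age_years = 40, abo = "A",
                hospital_x = 0, hospital_y = 0)
  run <- run_match(donor, pool)
  expect_identical(run$entries$candidate_id, c("hi", "lo"))
})

test_that("run_match handles an empty pool and is a permutation", {
  donor <- random_donor()
  empty <- run_match(donor, random_pool(5)[0, ])
  expect_s3_class(empty, "match_run")
  expect_identical(nrow(empty$entries), 0L)
  set.seed(11)
  pool <- random_pool(25)
  run <- run_match(donor, pool)
  expect_setequal(run$entries$candidate_id, pool$id)
  expect_identical(sort(run$entries$policy_rank), 1:25)
  expect_silent(validate_match_run(run))
})

test_that("run_match is deterministic byte-for-byte", {
  set.seed(3)
  pool <- random_pool(30)
  donor <- random_donor()
  a <- tempfile(fileext = ".csv")
  b <- tempfile(fileext = ".csv")
  write_match_runs(list(M1 = run_match(donor, pool)), a)
  write_match_runs(list(M1 = run_match(donor, pool)), b)
  expect_identical(readLines(a), readLines(b))
})

test_that("run_match agrees with the pairwise-comparator oracle", {
  set.seed(101)
  for (rep in 1:200) {
    n <- sample(1:8, 1)
    pool <- random_pool(n)
    donor <- random_donor()
    table <- if (donor$age_years >= 18) adult_policy_table()
             else pediatric_policy_table()
    run <- run_match(donor, pool, table)
    expect_identical(run$entries$candidate_id,
                     as.character(oracle_ranking(pool, donor, table)))
  }
})

test_that("adult runs never let a farther zone outrank a nearer one", {
  set.seed(5)
  donor <- list(id = "D", age_years = 45, abo = "O",
                hospital_x = 0, hospital_y = 0)
  for (rep in 1:20) {
    run <- run_match(donor, random_pool(40))
    e <- run$entries[order(run$entries$policy_rank), ]
    zone_idx <- match(e$zone, c("A", "B", "C", "D", "E", "F"))
    # adult-table cells are grouped by zone, so zone never decreases with rank
    expect_false(is.unsorted(zone_idx))
    expect_false(is.unsorted(e$classification_index))
  }
})
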