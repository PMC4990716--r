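origin <- as.Date("2013-04-01")

test_that("adherence metrics match their conventions on worked patterns", {
  # 28 consecutive on-time daily reports starting at the calendar origin
  m <- adherence_metrics(make_ratings("p1", 0:27, origin = origin),
                         calendar_origin = origin)
  expect_equal(unlist(m[, -1]), c(activeness = 28, timeliness = 28,
                                  duration = 1, persistence = 2))

  # reports on day 0 and day 15 only, both delayed
  m2 <- adherence_metrics(make_ratings("p2", c(0, 15), delay = 2L,
                                       origin = origin),
                          calendar_origin = origin)
  expect_equal(unlist(m2[, -1]), c(activeness = 2, timeliness = 0,
                                   duration = 1, persistence = 2))

  # a single report
  m3 <- adherence_metrics(make_ratings("p3", 5, origin = origin),
                          calendar_origin = origin)
  expect_equal(unlist(m3[, -1]), c(activeness = 1, timeliness = 1,
                                   duration = 0, persistence = 1))

  expect_error(adherence_metrics(make_ratings(character(), integer()),
                                 calendar_origin = origin), "no ratings")
})

test_that("timeliness counts a day by its earliest report", {
  # same day rated twice (two items), one on time and one delayed
  r <- dplyr::bind_rows(
    make_ratings("p1", 3, "mood", 3L, delay = 0L, origin = origin),
    make_ratings("p1", 3, "anxiety", 3L, delay = 2L, origin = origin))
  m <- adherence_metrics(r, calendar_origin = origin)
  expect_equal(m$activeness, 1L)
  expect_equal(m$timeliness, 1L)
})

test_that("adherence metric invariants hold over random reporting patterns", {
  withr::local_seed(301)
  for (i in 1:20) {
    days <- sort(sample(0:120, sample(2:40, 1)))
    delay <- sample(0:3, length(days), replace = TRUE)
    r <- make_ratings("px", days, delay = delay, origin = origin)
    m <- adherence_metrics(r, calendar_origin = origin)
    expect_lte(m$timeliness, m$activeness)
    # a span of d complete intervals touches at most d + 1 bins when bins
    # are anchored at the first report, and one more when the calendar
    # anchor splits the first partial interval
    expect_lte(m$persistence, m$duration + 2)
    m_anch <- adherence_metrics(r, calendar_origin = origin + min(days))
    expect_lte(m_anch$persistence, m_anch$duration + 1)
    expect_gte(m$persistence, 1)

    # adding a reported day never decreases activeness or persistence
    new_day <- setdiff(0:150, days)[1]
    r2 <- dplyr::bind_rows(r, make_ratings("px", new_day, origin = origin))
    m2 <- adherence_metrics(r2, calendar_origin = origin)
    expect_gte(m2$activeness, m$activeness)
    expect_gte(m2$persistence, m$persistence)

    # making one delayed day on-time raises timeliness by exactly 1
    late <- which(delay > 0)
    if (length(late) > 0) {
      delay3 <- delay
      delay3[late[1]] <- 0L
      m3 <- adherence_metrics(make_ratings("px", days, delay = delay3,
                                           origin = origin),
                              calendar_origin = origin)
      expect_equal(m3$timeliness, m$timeliness + 1L)
    }
  }
})

test_that("k-means recovers well-separated groups exactly", {
  # two clearly separated blobs in profile space
  withr::local_seed(303)
  profiles <- tibble::tibble(
    patient_id = sprintf("b%02d", 1:30),
    activeness = c(sample(140:170, 15, TRUE), sample(20:50, 15, TRUE)),
    timeliness = c(sample(100:130, 15, TRUE), sample(10:40, 15, TRUE)),
    duration = c(sample(12:16, 15, TRUE), sample(2:6, 15, TRUE)),
    persistence = c(sample(12:16, 15, TRUE), sample(2:6, 15, TRUE)))
  grouping <- label_groups(kmeans_cluster(profiles, k = 2, seed = 8),
                           profiles)
  expect_equal(unname(grouping), rep(c("higher", "lower"), each = 15))
})

test_that("clustering recovers most true adherence classes despite staggered entry", {
  co <- simulate_cohort(make_adherence_contrast_config(80, seed = 71))
  profiles <- adherence_profiles(co)
  grouping <- label_groups(kmeans_cluster(profiles, k = 2, seed = 8),
                           profiles)
  truth <- setNames(co$truth$classes$class, co$truth$classes$patient_id)
  # late-entering higher-adherence patients legitimately profile as lower,
  # so recovery is substantial but not exact
  agreement <- mean(grouping[names(truth)] == truth)
  expect_gt(agreement, 0.7)
})

test_that("k-means attains the exhaustive-partition optimum at n = 8", {
  withr::local_seed(302)
  profiles <- tibble::tibble(
    patient_id = sprintf("e%d", 1:8),
    activeness = c(10L, 12L, 15L, 90L, 95L, 100L, 50L, 55L),
    timeliness = c(8L, 9L, 12L, 70L, 80L, 90L, 40L, 42L),
    duration = c(2L, 3L, 2L, 12L, 13L, 14L, 7L, 8L),
    persistence = c(2L, 3L, 3L, 12L, 14L, 14L, 8L, 8L))
  model <- kmeans_cluster(profiles, k = 2, n_restarts = 50, seed = 9)
  X <- scale(as.matrix(profiles[, 2:5]))
  best <- Inf
  for (mask in 1:(2^7)) {            # all 2-partitions (up to relabeling)
    grp <- c(0, as.integer(intToBits(mask))[1:7])
    if (length(unique(grp)) < 2) next
    wcss <- sum(vapply(0:1, function(g) {
      Xi <- X[grp == g, , drop = FALSE]
      sum(sweep(Xi, 2, colMeans(Xi))^2)
    }, numeric(1)))
    best <- min(best, wcss)
  }
  expect_equal(model$wcss, best, tolerance = 1e-10)
})

test_that("k = n gives zero within-cluster sum of squares", {
  profiles <- adherence_profiles(
    simulate_cohort(sim_config(n_patients = 6, seed = 72)))
  model <- kmeans_cluster(profiles, k = nrow(profiles), seed = 10)
  expect_equal(model$wcss, 0)
})

test_that("best-of-restarts WCSS is nonincreasing in the restart count", {
  co <- simulate_cohort(make_adherence_contrast_config(60, seed = 73))
  profiles <- adherence_profiles(co)
  w1 <- kmeans_cluster(profiles, k = 3, n_restarts = 1, seed = 11)$wcss
  w25 <- kmeans_cluster(profiles, k = 3, n_restarts = 25, seed = 11)$wcss
  expect_lte(w25, w1)
})

test_that("zero-variance features are dropped with a warning", {
  profiles <- tibble::tibble(patient_id = c("a", "b", "c", "d"),
                             activeness = c(5L, 6L, 50L, 60L),
                             timeliness = c(4L, 5L, 40L, 50L),
                             duration = 3L, persistence = 3L)
  expect_warning(model <- kmeans_cluster(profiles, k = 2, seed = 12),
                 "duration, persistence")
  expect_setequal(model$features, c("activeness", "timeliness"))
})

test_that("cluster labels order by mean activeness with tie-breaks", {
  profiles <- tibble::tibble(
    patient_id = sprintf("p%d", 1:6),
    activeness = c(150L, 160L, 166L, 30L, 40L, 44L),
    timeliness = c(120L, 130L, 140L, 20L, 30L, 35L),
    duration = c(12L, 13L, 14L, 3L, 4L, 5L),
    persistence = c(12L, 13L, 14L, 3L, 4L, 5L))
  model <- kmeans_cluster(profiles, k = 2, seed = 13)
  grouping <- label_groups(model, profiles)
  expect_equal(unname(grouping[c("p1", "p4")]), c("higher", "lower"))

  # three strictly ordered clusters label higher/middle/lower
  profiles3 <- dplyr::bind_rows(
    profiles,
    tibble::tibble(patient_id = sprintf("m%d", 1:3),
                   activeness = c(90L, 95L, 100L), timeliness = c(70L, 75L,
                                                                  80L),
                   duration = c(8L, 8L, 9L), persistence = c(8L, 8L, 9L)))
  model3 <- kmeans_cluster(profiles3, k = 3, seed = 13)
  g3 <- label_groups(model3, profiles3)
  expect_equal(unname(g3[c("p1", "m1", "p4")]),
               c("higher", "middle", "lower"))

  # relabeling clusters changes nothing observable downstream
  expect_setequal(names(table(g3)), c("higher", "middle", "lower"))
})

test_that("response-rate grouping separates clear 1-D clusters", {
  ratings <- list()
  outcomes <- list()
  rates <- c(r1 = 14L, r2 = 13L, r3 = 3L, r4 = 2L)
  for (p in names(rates)) {
    days <- seq_len(rates[[p]])
    ratings[[p]] <- make_ratings(p, days, origin = origin)
    outcomes[[p]] <- make_phq9(p, 14, 8L, origin = origin)
  }
  tables <- cohort_tables(dplyr::bind_rows(ratings),
                          dplyr::bind_rows(outcomes))
  g <- response_rate_grouping(tables)
  expect_equal(unname(g[c("r1", "r2", "r3", "r4")]),
               c("higher", "higher", "lower", "lower"))
})

test_that("uniform full reporting degenerates to a single response-rate group", {
  ratings <- dplyr::bind_rows(lapply(c("u1", "u2", "u3"), function(p) {
    make_ratings(p, 1:14, origin = origin)
  }))
  outcomes <- dplyr::bind_rows(lapply(c("u1", "u2", "u3"), function(p) {
    make_phq9(p, 14, 8L, origin = origin)
  }))
  tables <- cohort_tables(ratings, outcomes)
  expect_warning(g <- response_rate_grouping(tables), "identical")
  expect_true(all(g == "higher"))
})

test_that("composite and response-rate groupings can disagree", {
  # a patient reporting 14/14 in a single fortnight and nothing after has a
  # perfect response rate but minimal persistence
  co <- simulate_cohort(make_adherence_contrast_config(50, seed = 74))
  burst <- make_ratings("burst", 1:14,
                        origin = min(co$tables$ratings$target_date) - 1)
  burst_out <- make_phq9("burst", 14,
                         8L, origin = min(co$tables$ratings$target_date) - 1)
  tables <- suppressWarnings(cohort_tables(
    dplyr::bind_rows(co$tables$ratings, burst),
    dplyr::bind_rows(co$tables$outcomes, burst_out)))
  rate_g <- response_rate_grouping(tables)
  profiles <- adherence_profiles(tables)
  comp_g <- label_groups(kmeans_cluster(profiles, k = 2, seed = 14),
                         profiles)
  expect_equal(unname(rate_g["burst"]), "higher")
  expect_equal(unname(comp_g["burst"]), "lower")
})

test_that("identical data in both groups compare as equal", {
  co <- simulate_cohort(sim_config(n_patients = 30, seed = 75))
  pats <- unique(co$tables$outcomes$patient_id)
  # duplicate every patient into a mirrored id so both groups hold the same data
  mirror <- function(df) {
    df2 <- df
    df2$patient_id <- paste0(df2$patient_id, "_m")
    dplyr::bind_rows(df, df2)
  }
  tables <- cohort_tables(mirror(co$tables$ratings),
                          mirror(co$tables$outcomes))
  grouping <- setNames(rep(c("higher", "lower"), each = length(pats)),
                       c(pats, paste0(pats, "_m")))
  res <- suppressWarnings(suppressMessages(
    group_auc_comparison(tables, grouping, "average")))
  expect_equal(res$comparison$statistic, 0, tolerance = 1e-12)
  expect_equal(res$comparison$auc_1, res$comparison$auc_2)
})

test_that("empty or degenerate groups error with the group name", {
  co <- simulate_cohort(sim_config(n_patients = 10, seed = 76))
  pats <- unique(co$tables$outcomes$patient_id)
  g_all_high <- setNames(rep("higher", length(pats)), pats)
  expect_error(group_auc_comparison(co, g_all_high, "average"),
               "'lower' is empty")
})

test_that("robustness filters truncate and exclude as documented", {
  r30 <- make_ratings("long", 0:209, origin = origin)       # 30 weeks
  late <- make_ratings("late", 330:335, origin = origin)
  early <- make_ratings("early", 0:5, origin = origin)
  ratings <- dplyr::bind_rows(r30, late, early)
  outcomes <- dplyr::bind_rows(
    make_phq9("long", 14 * (1:15), 8L, origin = origin),
    make_phq9("late", 336, 8L, origin = origin),
    make_phq9("early", 14, 8L, origin = origin))
  tables <- cohort_tables(ratings, outcomes)

  # identity
  expect_identical(robustness_filters(tables, "none"), tables)

  # per-patient truncation to the first 24 weeks (168 days)
  tr <- robustness_filters(tables, "first_24_weeks")
  long_days <- tr$ratings$target_date[tr$ratings$patient_id == "long"]
  expect_equal(max(as.integer(long_days - min(long_days))), 167L)
  expect_equal(sum(tr$outcomes$patient_id == "long"), 11L)
  # a short patient is untouched
  expect_equal(sum(tr$ratings$patient_id == "early"), 6L)

  # late starters (first report within the final 84 days) are removed
  dl <- robustness_filters(tables, "drop_late_starters")
  expect_false("late" %in% dl$ratings$patient_id)
  expect_true(all(c("long", "early") %in% dl$ratings$patient_id))
  expect_false("late" %in% dl$outcomes$patient_id)
})
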