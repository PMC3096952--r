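test_that("staircaseAUC counts strict case-over-control orderings", {
  expect_equal(staircaseAUC(c(3, 1), c(2, 0)), 0.75)  # 3 of 4 pairs ordered
  expect_equal(staircaseAUC(c(5, 6), c(1, 2)), 1)
  expect_equal(staircaseAUC(c(1, 1), c(1, 1)), 0)            # ties -> 0
  expect_equal(staircaseAUC(c(1, 1), c(1, 1), ties = "half"), 0.5)
  expect_error(staircaseAUC(numeric(0), 1), "non-empty")
})

test_that("atdAUC handles the canonical concordant/anti-concordant cases", {
  s <- atdAUC(c(4, 3, 2, 1), time = 1:4, event = c(1, 1, 0, 0))
  expect_equal(s@value, 1)
  expect_identical(s@nEventsAveraged, 2L)
  expect_equal(atdAUC(c(1, 2, 3, 4), time = 1:4,
                      event = c(1, 1, 0, 0))@value, 0)
  # per-time bookkeeping: cases cumulate, controls shrink
  expect_equal(s@curve$n_cases, c(1, 2))
  expect_equal(s@curve$n_controls, c(3, 2))
  expect_true(all(s@curve$included))
})

test_that("the last event time without controls is recorded but excluded", {
  s <- atdAUC(c(3, 2, 1), time = c(1, 2, 3), event = c(1, 0, 1))
  expect_identical(sum(!s@curve$included), 1L)
  expect_identical(s@nEventsAveraged, 1L)
  expect_error(atdAUC(c(1, 2), time = c(1, 2), event = c(0, 1)),
               "unevaluable")
  expect_error(atdAUC(c(1, 2), time = c(1, 2), event = c(0, 0)), "no events")
})

test_that("atdAUC equals brute-force enumeration on random small instances", {
  set.seed(101)
  checked <- 0
  while (checked < 120) {
    inst <- randomInstance(sample(4:30, 1))
    if (!evaluableInstance(inst)) next
    checked <- checked + 1
    for (ties in c("strict", "half")) {
      expected <- bruteATD(inst$scores, inst$time, inst$event, ties)
      expect_identical(atdAUC(inst$scores, inst$time, inst$event,
                              ties = ties)@value, expected)
      # internal fast path must agree bitwise with the reference path
      expect_identical(prognest:::.atdValue(inst$scores, inst$time,
                                            inst$event, ties), expected)
    }
  }
})

test_that("atdAUC is invariant under strictly increasing score transforms", {
  set.seed(77)
  for (i in 1:20) {
    inst <- randomInstance(25)
    if (!evaluableInstance(inst)) next
    v <- atdAUC(inst$scores, inst$time, inst$event)@value
    expect_equal(atdAUC(exp(inst$scores / 2), inst$time, inst$event)@value, v)
    expect_equal(atdAUC(rank(inst$scores, ties.method = "min") + 100,
                        inst$time, inst$event)@value, v)
  }
})

test_that("score reversal complements the AUC when no ties occur", {
  set.seed(55)
  for (i in 1:20) {
    n <- 20
    scores <- sample(seq_len(1000), n)  # distinct -> no tied pairs
    time <- sample(1:8, n, replace = TRUE) + 0
    event <- rbinom(n, 1, 0.5)
    if (!any(event == 1) || !any(time[event == 1] < max(time))) next
    v <- atdAUC(scores, time, event)@value
    expect_equal(atdAUC(-scores, time, event)@value, 1 - v)
  }
})

test_that("uninformative scores give AUC near one half", {
  set.seed(3)
  vals <- replicate(200, {
    n <- 80
    time <- rexp(n, 0.1) + 0.01
    event <- rbinom(n, 1, 0.6)
    if (!any(event == 1) || !any(time[event == 1] < max(time))) return(NA)
    atdAUC(rnorm(n), time, event)@value
  })
  expect_equal(mean(vals, na.rm = TRUE), 0.5, tolerance = 0.02)
})
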