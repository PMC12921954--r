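# Event data model, I/O, slicing, alignment, balancing, user splits.

test_that("readEvents sorts by timestamp and handles empty files", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# width=8 height=8", "t,x,y,p",
               "0,1,1,1", "10,2,2,-1", "5,3,3,1", "20,4,4,1"), f)
  s <- readEvents(f)
  expect_equal(eventData(s)$t, c(0, 5, 10, 20))
  expect_equal(unname(sensorSize(s)), c(8, 8))

  fe <- withr::local_tempfile(fileext = ".csv")
  writeLines("# width=8 height=8", fe)
  se <- readEvents(fe)
  expect_equal(nEvents(se), 0L)
  expect_equal(unname(timeSpan(se)), c(0, 0))
})

test_that("malformed rows and out-of-geometry coordinates are rejected", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# width=8 height=8", "t,x,y,p", "0,1,1,1", "5,oops,1,1"), f)
  expect_error(readEvents(f), "malformed|row")
  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# width=8 height=8", "t,x,y,p", "0,9,1,1"), g)
  expect_error(readEvents(g), "geometry")
})

test_that("write/read round-trips preserve every record in both dialects", {
  s <- tinyStream(n = 1000, width = 32, height = 24, seed = 11)
  for (ext in c(".csv", ".feather")) {
    f <- withr::local_tempfile(fileext = ext)
    writeEvents(s, f)
    r <- readEvents(f)
    expect_equal(eventData(r), eventData(s), ignore_attr = TRUE)
    expect_equal(unname(sensorSize(r)), c(32, 24))
  }
})

test_that("sliceStream uses half-open windows and is idempotent", {
  s <- EventStream(data.frame(t = c(0, 5, 10), x = 0:2, y = 0L,
                              p = 1L), 8, 8)
  expect_equal(nEvents(sliceStream(s, 0, 10)), 2L)           # [0, 10)
  expect_equal(nEvents(sliceStream(s, 0, 11)), 3L)
  expect_error(sliceStream(s, 5, 5), "t0 < t1")

  full <- sliceStream(s, 0, 11)
  expect_equal(eventData(full), eventData(s), ignore_attr = TRUE)
  # empty window before the first event beyond epsilon
  s2 <- EventStream(data.frame(t = c(100, 200), x = 0:1, y = 0L, p = 1L),
                    8, 8, tStart = 0, tEnd = 300)
  expect_equal(nEvents(sliceStream(s2, 0, 1)), 0L)
  # idempotence
  a <- sliceStream(s, 2, 9)
  b <- sliceStream(a, 2, 9)
  expect_equal(eventData(a), eventData(b), ignore_attr = TRUE)
})

test_that("alignLabels partitions events exactly and keeps empty segments", {
  s <- tinyStream(n = 200, seed = 3, tMax = 1e5)
  iv <- data.frame(tStart = c(0, 4e4, 9e4), tEnd = c(4e4, 9e4, 9.5e4),
                   label = c("fixation", "saccade", "fixation"))
  segs <- alignLabels(s, iv, rezero = FALSE)
  expect_length(segs, 3L)
  covered <- sum(eventData(s)$t < 9.5e4)
  expect_equal(sum(vapply(segs, nEvents, 1L)), covered)
  # conservation: each covered event appears exactly once
  allT <- sort(unlist(lapply(segs, function(g) eventData(segmentStream(g))$t)))
  expect_equal(allT, sort(eventData(s)$t[eventData(s)$t < 9.5e4]))
  # empty interval retained and flagged
  iv2 <- rbind(iv, data.frame(tStart = 9.9e4, tEnd = 1e5, label = "saccade"))
  segs2 <- alignLabels(s, iv2, rezero = FALSE)
  expect_length(segs2, 4L)
  expect_true(is.logical(attr(segs2, "empty")))
  # overlapping intervals rejected
  bad <- data.frame(tStart = c(0, 3e4), tEnd = c(5e4, 6e4),
                    label = c("fixation", "saccade"))
  expect_error(alignLabels(s, bad), "overlap")
})

test_that("balanceClasses draws exact seeded counts and errors when short", {
  mk <- function(lbl, n) replicate(n, LabeledSegment(tinyStream(5), lbl),
                                   simplify = FALSE)
  segs <- c(mk("saccade", 12), mk("fixation", 8))
  bal <- balanceClasses(segs, 8, seed = 4)
  labs <- vapply(bal, segmentLabel, "")
  expect_equal(sum(labs == "saccade"), 8L)
  expect_equal(sum(labs == "fixation"), 8L)
  # identity when n equals class size
  bal2 <- balanceClasses(segs, 8, seed = 9)
  expect_true(all(vapply(bal2, segmentLabel, "") %in% c("fixation", "saccade")))
  expect_equal(sum(vapply(bal2, segmentLabel, "") == "fixation"), 8L)
  # determinism
  expect_identical(lapply(balanceClasses(segs, 6, seed = 2), nEvents),
                   lapply(balanceClasses(segs, 6, seed = 2), nEvents))
  sel1 <- vapply(balanceClasses(segs, 6, seed = 2), segmentLabel, "")
  sel2 <- vapply(balanceClasses(segs, 6, seed = 2), segmentLabel, "")
  expect_identical(sel1, sel2)
  expect_error(balanceClasses(segs, 10, seed = 1), "fixation")
})

test_that("splitByUser assigns by user id, disjointly, with counting", {
  segs <- unlist(lapply(1:10, function(u)
    replicate(20, LabeledSegment(tinyStream(3), "fixation", userId = u),
              simplify = FALSE)), recursive = FALSE)
  sp <- splitByUser(segs, 1:7, 8:10)
  expect_length(sp$train, 140L)
  expect_length(sp$test, 60L)
  expect_length(intersect(unique(vapply(sp$train, userId, 1L)),
                          unique(vapply(sp$test, userId, 1L))), 0L)
  # all users in train, none in test
  sp2 <- splitByUser(segs, 1:10, integer(0))
  expect_length(sp2$train, 200L)
  expect_length(sp2$test, 0L)
  # unlisted users excluded with warning
  expect_warning(sp3 <- splitByUser(segs, 1:5, 6:8), "unlisted")
  expect_length(sp3$train, 100L)
  expect_error(splitByUser(segs, 1:5, 5:8), "disjoint")
})
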