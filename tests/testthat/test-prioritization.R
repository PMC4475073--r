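## build a change_table by hand, bypassing the pipeline
fake_change <- function(avail, change, transition = "later-earlier") {
  out <- data.frame(cell_id = seq_along(avail))
  out[[transition]] <- change
  out[[paste0("avail:", transition)]] <- avail
  structure(out, transitions = transition,
            class = c("change_table", "data.frame"))
}

test_that("temporal change is the later-minus-earlier difference per cell", {
  fake <- structure(list(
    cells = data.frame(id = 1:3, q = 0:2, r = 0, cx = 0, cy = 0,
                       interior = TRUE),
    adjacency = data.frame(i = c(1, 2), j = c(2, 3)),
    values = list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(4, 1, 3)),
    cell_area_ha = 5000, res = 50, s = 1, extent = c(0, 1, 0, 1)),
    class = "focal_grid")
  imp <- regional_importance(fake, c("a", "b", "c"))
  chg <- temporal_change(imp, fake)
  # identical importance between a and b: change 0
  expect_equal(chg[["b-a"]], c(0, 0, 0))
  # three periods: two consecutive transitions plus overall
  expect_equal(attr(chg, "transitions"), c("b-a", "c-b", "c-a"))
  expect_equal(chg[["c-b"]], imp$c - imp$b)
  # availability column carries the earlier period's local values
  expect_equal(chg[["avail:c-b"]], c(1, 2, 3))
  expect_error(temporal_change(imp, fake, list(c("a", "z"))), "unknown period")

  # a cell going from 10% to 4% changes by -6 points
  imp2 <- structure(data.frame(cell_id = 1, p1 = 10, p2 = 4),
                    periods = c("p1", "p2"),
                    class = c("importance_table", "data.frame"))
  fake2 <- fake; fake2$values <- list(p1 = 5, p2 = 5)
  fake2$cells <- fake$cells[1, ]
  expect_equal(temporal_change(imp2, fake2)[["p2-p1"]], -6)
})

test_that("four periods give exactly three consecutive transitions plus overall", {
  fake <- structure(list(
    cells = data.frame(id = 1:2, q = 0:1, r = 0, cx = 0, cy = 0,
                       interior = TRUE),
    adjacency = data.frame(i = 1, j = 2),
    values = list(current = c(1, 2), `2030` = c(2, 1), `2050` = c(1, 3),
                  `2080` = c(3, 1)),
    cell_area_ha = 5000, res = 50, s = 1, extent = c(0, 1, 0, 1)),
    class = "focal_grid")
  imp <- regional_importance(fake, c("current", "2030", "2050", "2080"))
  chg <- temporal_change(imp, fake)
  expect_equal(attr(chg, "transitions"),
               c("2030-current", "2050-2030", "2080-2050", "2080-current"))
})

test_that("the six-class rule table reproduces the worked example", {
  chg <- fake_change(avail = c(10, 9, 8, 3, 2, 1),
                     change = c(-2, 1, 4, -3, 1, 4))
  sm <- classify_strategies(chg)
  # M_a = 5.5, M_d = median(1,4,1,4) = 2.5
  expect_equal(as.character(sm[["later-earlier"]]),
               c("II", "III", "IV", "I", "V", "VI"))
  th <- attr(sm, "thresholds")[["later-earlier"]]
  expect_equal(th$median_availability, 5.5)
  expect_equal(th$median_positive_change, 2.5)
  expect_equal(length(unique(sm[["later-earlier"]])), 6L)
})

test_that("ties and degenerate tables resolve deterministically", {
  # all cells identical: availability ties at the median go to the >= branch
  # (all-zero change also means no positive split, hence the warning)
  expect_warning(same <- classify_strategies(fake_change(rep(4, 5), rep(0, 5))),
                 "restoration split")
  expect_true(all(same[["later-earlier"]] == "II"))
  # single increasing cell ties at both medians: class IV
  one <- classify_strategies(fake_change(7, 2))
  expect_equal(as.character(one[["later-earlier"]]), "IV")
  # no positive change anywhere: warning, only conservation/no-action classes
  expect_warning(dec <- classify_strategies(
    fake_change(c(5, 1), c(-1, -2))), "restoration split")
  expect_true(all(as.character(dec[["later-earlier"]]) %in% c("I", "II")))
  expect_error(classify_strategies(fake_change(numeric(0), numeric(0))),
               "no cells")
})

test_that("classification partitions all cells and is scale equivariant", {
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(4:40, 1)
    avail <- runif(n, 0, 100)
    change <- rnorm(n, 0, 5)
    sm <- classify_strategies(fake_change(avail, change))
    cls <- sm[["later-earlier"]]
    expect_false(anyNA(cls))                        # exhaustive
    expect_true(all(cls %in% c("I", "II", "III", "IV", "V", "VI")))
    # availability split: II-IV above median, I/V/VI below
    hi <- avail >= median(avail)
    expect_true(all(cls[hi] %in% c("II", "III", "IV")))
    expect_true(all(cls[!hi] %in% c("I", "V", "VI")))
    # multiplying availability by a positive constant changes nothing
    sm2 <- classify_strategies(fake_change(avail * 13.7, change))
    expect_equal(as.character(sm2[["later-earlier"]]), as.character(cls))
  }
})

test_that("raising a cell's change never demotes its restoration priority", {
  rank_of <- c(I = 1, V = 2, VI = 3, II = 1, III = 2, IV = 3)
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(5:15, 1)
    avail <- runif(n); change <- rnorm(n)
    base <- suppressWarnings(classify_strategies(fake_change(avail, change)))
    k <- sample(n, 1)
    bumped <- change; bumped[k] <- bumped[k] + runif(1, 0, 3)
    after <- suppressWarnings(classify_strategies(fake_change(avail, bumped)))
    expect_gte(rank_of[as.character(after[["later-earlier"]][k])],
               rank_of[as.character(base[["later-earlier"]][k])])
  }
})

test_that("strategy maps export to GeoJSON and round-trip", {
  grid <- hex_tessellation(c(0, 30000, 0, 30000), cell_area_ha = 5000)
  n <- nrow(grid$cells)
  avail <- seq_len(n); change <- rep(c(-2, 1, 4), length.out = n)
  chg <- fake_change(avail, change, transition = "t2-t1")
  chg$cell_id <- grid$cells$id
  sm <- classify_strategies(chg)
  f <- withr::local_tempfile(fileext = ".geojson")
  write_strategy_geojson(sm, grid, f)
  back <- read_strategy_geojson(f)
  expect_equal(nrow(back), n)
  expect_equal(back[["class_t2.t1"]], as.character(sm[["t2-t1"]]))
  gj <- jsonlite::read_json(f)
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features[[1]]$geometry$coordinates[[1]], 7)  # closed ring
  expect_false(is.null(gj$thresholds[["t2-t1"]]))

  # id mismatch rejected; empty table gives a valid empty layer
  bad <- sm; bad$cell_id[1] <- 10 * n + 99
  expect_error(write_strategy_geojson(bad, grid, f), "absent")
  empty <- structure(data.frame(cell_id = integer(0)),
                     transitions = character(0), thresholds = list(),
                     class = c("strategy_map", "data.frame"))
  f2 <- withr::local_tempfile(fileext = ".geojson")
  write_strategy_geojson(empty, grid, f2)
  expect_equal(nrow(read_strategy_geojson(f2)), 0L)
})
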