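#' Temporal change in regional importance (ddIIC)
#'
#' Differences each cell's regional importance (dIIC) between period pairs:
#' `ddIIC = dIIC(later) - dIIC(earlier)`, in percentage points. A positive
#' value means the cell's importance for regional dispersal grows under the
#' later climate. The default transition scheme is every consecutive period
#' pair plus the overall first-to-last trend. Each transition also carries
#' the cells' habitat availability (local PC numerator) in its *earlier*
#' period, which the strategy classifier splits on.
#'
#' @param importance an `importance_table` from [regional_importance()].
#' @param grid the [focal_grid] holding the per-period local PC numerators.
#' @param transitions list of `c(earlier, later)` period-label pairs;
#'   default: consecutive pairs plus overall.
#' @return A `change_table`: data.frame with `cell_id`, one ddIIC column per
#'   transition (named `"later-earlier"`), plus matching availability
#'   columns (`avail:<transition>`).
#' @export
temporal_change <- function(importance, grid, transitions = NULL) {
  stopifnot(inherits(importance, "importance_table"),
            inherits(grid, "focal_grid"))
  periods <- attr(importance, "periods")
  if (is.null(transitions)) {
    transitions <- lapply(seq_len(length(periods) - 1),
                          function(i) c(periods[i], periods[i + 1]))
    if (length(periods) > 2)
      transitions <- c(transitions, list(c(periods[1], periods[length(periods)])))
  }
  out <- data.frame(cell_id = importance$cell_id)
  labels <- character(0)
  for (tr in transitions) {
    if (!all(tr %in% periods))
      stop("unknown period label(s): ", paste(setdiff(tr, periods), collapse = ", "))
    if (!all(tr %in% names(grid$values)))
      stop("focal grid lacks local values for: ",
           paste(setdiff(tr, names(grid$values)), collapse = ", "))
    lbl <- paste0(tr[2], "-", tr[1])
    labels <- c(labels, lbl)
    out[[lbl]] <- importance[[tr[2]]] - importance[[tr[1]]]
    out[[paste0("avail:", lbl)]] <- grid$values[[tr[1]]]
  }
  structure(out, transitions = labels,
            class = c("change_table", "data.frame"))
}

strategy_class_labels <- c(
  I   = "No action",
  II  = "Short-term conservation",
  III = "Low priority restoration / long-term conservation",
  IV  = "Long-term conservation",
  V   = "Intermediate priority restoration",
  VI  = "High priority restoration")

#' Six-class conservation/restoration strategy classifier
#'
#' Assigns each focal landscape, per transition, to one of six strategy
#' classes from two axes: current habitat availability (the earlier period's
#' local PC numerator) split at its median `M_a` over all cells, and the
#' change in regional importance (ddIIC) split at zero and at `M_d`, the
#' median of the *strictly positive* changes — so that restoration effort is
#' directed only at cells whose conditions are genuinely improving:
#'
#' | availability | ddIIC <= 0 | 0 < ddIIC < M_d | ddIIC >= M_d |
#' |--------------|-----------|-----------------|--------------|
#' | >= M_a       | II short-term conservation | III low-priority restoration / long-term conservation | IV long-term conservation |
#' | <  M_a       | I no action | V intermediate restoration | VI high-priority restoration |
#'
#' Median ties resolve upward (`>=`), favoring action over inaction; zero
#' change groups with decreases. If no cell shows a positive change the
#' restoration split is undefined and any increasing cells are routed to
#' class V with a warning.
#'
#' @param change a `change_table` from [temporal_change()].
#' @return A `strategy_map`: data.frame with `cell_id` and one factor column
#'   (levels `I`..`VI`) per transition; the thresholds used are stored in
#'   `attr(, "thresholds")`.
#' @export
classify_strategies <- function(change) {
  stopifnot(inherits(change, "change_table"))
  if (!nrow(change)) stop("change table has no cells")
  transitions <- attr(change, "transitions")
  out <- data.frame(cell_id = change$cell_id)
  thresholds <- list()
  for (tr in transitions) {
    d <- change[[tr]]
    avail <- change[[paste0("avail:", tr)]]
    M_a <- stats::median(avail)
    pos <- d[d > 0]
    M_d <- if (length(pos)) stats::median(pos) else NA_real_
    if (!length(pos))
      warning("no positive ddIIC for '", tr,
              "'; restoration split undefined (any increasing cell would go to V)")
    high <- avail >= M_a
    cls <- ifelse(d <= 0,
                  ifelse(high, "II", "I"),
                  ifelse(!is.na(M_d) & d >= M_d,
                         ifelse(high, "IV", "VI"),
                         ifelse(high, "III", "V")))
    out[[tr]] <- factor(cls, levels = names(strategy_class_labels))
    thresholds[[tr]] <- list(median_availability = M_a,
                             median_positive_change = M_d)
  }
  structure(out, transitions = transitions, thresholds = thresholds,
            class = c("strategy_map", "data.frame"))
}

#' @export
print.strategy_map <- function(x, ...) {
  cat("<strategy_map> ", nrow(x), " cell(s), transitions: ",
      paste(attr(x, "transitions"), collapse = ", "), "\n", sep = "")
  for (tr in attr(x, "transitions")) {
    tab <- table(x[[tr]])
    cat("  ", tr, ": ", paste(names(tab), tab, sep = "=", collapse = " "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Export a strategy map (or focal grid) as GeoJSON
#'
#' Writes one polygon feature per hexagon cell with its class code and label
#' per transition; the medians used as thresholds are recorded in the
#' feature collection's `thresholds` member. The file is plain GeoJSON and
#' loads in any GIS.
#'
#' @param strategy a `strategy_map` from [classify_strategies()].
#' @param grid the matching [focal_grid].
#' @param path output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_strategy_geojson <- function(strategy, grid, path) {
  stopifnot(inherits(strategy, "strategy_map"), inherits(grid, "focal_grid"))
  if (!all(strategy$cell_id %in% grid$cells$id))
    stop("strategy table refers to cell ids absent from the grid")
  transitions <- attr(strategy, "transitions")
  features <- lapply(seq_len(nrow(strategy)), function(k) {
    id <- strategy$cell_id[k]
    v <- hex_vertices(grid, id)
    ring <- rbind(v, v[1, , drop = FALSE])
    props <- list(cell_id = id)
    for (tr in transitions) {
      cls <- as.character(strategy[[tr]][k])
      props[[paste0("class_", tr)]] <- cls
      props[[paste0("label_", tr)]] <- unname(strategy_class_labels[cls])
    }
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  })
  fc <- list(type = "FeatureCollection",
             thresholds = attr(strategy, "thresholds"),
             features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read back a strategy GeoJSON written by [write_strategy_geojson()]
#'
#' @param path a `.geojson` file.
#' @return A data.frame with `cell_id` and the class columns.
#' @export
read_strategy_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!length(fc$features))
    return(data.frame(cell_id = integer(0)))
  rows <- lapply(fc$features, function(f)
    as.data.frame(f$properties, stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
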