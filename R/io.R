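#' Read and validate a tree table
#'
#' Required columns: `tree_id`, `x`, `y`, `di`, `species`, `dbh`, `height`;
#' optional `decay_stage`. Errors name the offending row and column.
#'
#' @param path CSV file path.
#' @return validated data.frame with `species` as a factor.
#' @export
read_trees <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("tree_id", "x", "y", "di", "species", "dbh", "height")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("trees file missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  for (cc in c("x", "y", "di", "dbh", "height")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(d[[cc]]))))
    if (length(bad)) stop(sprintf("non-numeric value in column '%s', row %d",
                                  cc, bad[1]), call. = FALSE)
    d[[cc]] <- as.numeric(d[[cc]])
  }
  if (any(d$dbh <= 0) || any(d$height <= 0))
    stop("dbh and height must be > 0", call. = FALSE)
  if (anyDuplicated(d$tree_id))
    stop("duplicate tree_id at row ", anyDuplicated(d$tree_id), call. = FALSE)
  d$species <- factor(d$species, levels = SPECIES_LEVELS)
  if (anyNA(d$species)) stop("unknown species level in trees file",
                             call. = FALSE)
  d
}

#' Read and validate a routes table
#'
#' Required columns: `route_id`, `woodpecker_id`, `step`, `tree_id`,
#' `arrival_min`, `departure_min`, `behavior`, `family_size`; optional
#' `censored`. Enforces: departure >= arrival, behaviour in {F, O}, unique
#' and contiguous steps per route, and distinct trees on consecutive steps.
#' Routes shorter than `min_route_length` trees are dropped with a message.
#'
#' @param path CSV file path.
#' @param min_route_length minimum trees per route (default 6, matching the
#'   field protocol of discarding short behavioural sequences).
#' @return validated data.frame.
#' @export
read_routes <- function(path, min_route_length = 6) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("route_id", "woodpecker_id", "step", "tree_id", "arrival_min",
            "departure_min", "behavior", "family_size")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("routes file missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(d$censored)) d$censored <- FALSE
  key <- paste(d$route_id, d$step)
  if (anyDuplicated(key))
    stop("duplicate (route_id, step) at row ", anyDuplicated(key),
         call. = FALSE)
  if (any(d$departure_min < d$arrival_min))
    stop("departure before arrival at row ",
         which(d$departure_min < d$arrival_min)[1], call. = FALSE)
  if (!all(d$behavior %in% c("F", "O")))
    stop("behavior must be 'F' or 'O' (row ",
         which(!d$behavior %in% c("F", "O"))[1], ")", call. = FALSE)
  keep <- NULL
  dropped <- 0L
  for (rid in unique(d$route_id)) {
    rr <- d[d$route_id == rid, ]
    rr <- rr[order(rr$step), ]
    if (!identical(rr$step, seq_len(nrow(rr))) &&
        !identical(as.integer(rr$step), seq_len(nrow(rr))))
      stop("steps not contiguous from 1 in route ", rid, call. = FALSE)
    if (nrow(rr) > 1 && any(rr$tree_id[-1] == rr$tree_id[-nrow(rr)]))
      stop("same tree on consecutive steps in route ", rid, call. = FALSE)
    if (nrow(rr) < min_route_length) { dropped <- dropped + 1L; next }
    keep <- rbind(keep, rr)
  }
  if (dropped > 0)
    message(dropped, " route(s) with fewer than ", min_route_length,
            " trees discarded")
  if (is.null(keep)) stop("no route satisfies the minimum length",
                          call. = FALSE)
  rownames(keep) <- NULL
  keep
}

#' Read an S2-style used-tree table
#'
#' The deposited supplementary format: columns `PSRI` (untransformed index
#' for every tree record), `Tree.stage` (0 = unused, 1 = used for foraging,
#' 2 = used for other behaviour), `Time` (step along the route) and
#' `Route`. This dialect carries no coordinates or covariates, so it only
#' supports count-based checks. XLSX is not supported offline; convert to
#' CSV first.
#'
#' @param path CSV file path.
#' @return data.frame with the four validated columns.
#' @seealso [s2_counts()]
#' @export
read_s2 <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("PSRI", "Tree.stage", "Time", "Route")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("S2 file missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(!d$Tree.stage %in% 0:2)
  if (length(bad)) stop("invalid Tree.stage (must be 0, 1 or 2) at row ",
                        bad[1], call. = FALSE)
  if (any(!is.finite(suppressWarnings(as.numeric(d$PSRI)))))
    stop("non-numeric PSRI", call. = FALSE)
  d
}

#' Row counts of an S2-style table
#'
#' @param s2 output of [read_s2()].
#' @return named vector: `total` rows, `used` (stage 1 or 2), `foraging`
#'   (stage 1), `routes` (distinct route ids).
#' @export
s2_counts <- function(s2) {
  c(total = nrow(s2),
    used = sum(s2$Tree.stage %in% c(1, 2)),
    foraging = sum(s2$Tree.stage == 1),
    routes = length(unique(s2$Route)))
}

#' @rdname read_trees
#' @param trees tree table to write.
#' @param path output CSV path.
#' @export
write_trees <- function(trees, path) {
  write.csv(trees, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_routes
#' @param routes routes table to write.
#' @export
write_routes <- function(routes, path) {
  write.csv(routes, path, row.names = FALSE)
  invisible(path)
}
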