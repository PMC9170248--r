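#' Build a bipartite rod/cone contact graph
#'
#' The connectivity substrate for all graph metrics: rod and cone id sets, a
#' deduplicated edge list, per-cone telodendrial-field areas, the region area,
#' and the subset of central cones used to avoid edge artifacts (mirroring the
#' central-13 restriction applied to the EM reconstruction).
#'
#' @param contacts data.frame with `rod_id`, `cone_id` (repeated pads collapse
#'   to one edge; multiplicity lives in the gap-junction table).
#' @param cone_ids character vector of all cone ids.
#' @param rod_ids character vector of all rod ids.
#' @param cone_field_area named numeric vector, um^2 per cone.
#' @param region_area region area, um^2.
#' @param central_cone_ids subset of `cone_ids` used for edge-corrected
#'   summaries; defaults to all cones.
#' @return Object of class `contact_graph`.
#' @export
contact_graph <- function(contacts, cone_ids, rod_ids, cone_field_area = NULL,
                          region_area = NA_real_,
                          central_cone_ids = cone_ids) {
  edges <- unique(contacts[, c("rod_id", "cone_id")])
  if (!all(edges$rod_id %in% rod_ids))
    stop("edge references unknown rod id(s): ",
         paste(utils::head(setdiff(edges$rod_id, rod_ids)), collapse = ", "))
  if (!all(edges$cone_id %in% cone_ids))
    stop("edge references unknown cone id(s): ",
         paste(utils::head(setdiff(edges$cone_id, cone_ids)), collapse = ", "))
  if (!all(central_cone_ids %in% cone_ids))
    stop("central_cone_ids must be a subset of cone_ids")
  if (!is.null(cone_field_area) && any(cone_field_area <= 0, na.rm = TRUE))
    stop("cone field areas must be positive")
  structure(
    list(edges = edges, cone_ids = cone_ids, rod_ids = rod_ids,
         cone_field_area = cone_field_area, region_area = region_area,
         central_cone_ids = central_cone_ids),
    class = "contact_graph"
  )
}

#' Contact graph from a synthetic scene
#'
#' Convenience constructor: takes ids, edges, field areas, and region area
#' from an `opl_scene` and selects central cones as those whose field polygon
#' lies entirely inside the region shrunk by `margin` (default: the mean field
#' radius), the same edge-artifact correction as restricting to interior
#' pedicles.
#'
#' @param scene an `opl_scene`.
#' @param margin border margin in um for central-cone selection.
#' @return A [contact_graph()].
#' @export
scene_contact_graph <- function(scene, margin = NULL) {
  cones <- scene$cones
  region <- attr(cones, "region")
  if (is.null(margin))
    margin <- sqrt(mean(cones$area_um2) / pi)
  polys <- cone_polygons(cones)
  central <- vapply(cones$id, function(id) {
    p <- polys[[id]]
    all(p[, 1] >= margin & p[, 1] <= region[["width"]] - margin &
        p[, 2] >= margin & p[, 2] <= region[["height"]] - margin)
  }, logical(1))
  # small regions may leave no field fully interior; fall back to all cones
  central_ids <- if (any(central)) cones$id[central] else cones$id
  contact_graph(
    scene$contacts, cone_ids = cones$id, rod_ids = scene$rods$id,
    cone_field_area = stats::setNames(cones$area_um2, cones$id),
    region_area = region[["width"]] * region[["height"]],
    central_cone_ids = central_ids
  )
}

#' Convergence: rod contacts per cone
#'
#' @param graph a [contact_graph()].
#' @param cone_subset cones to summarize over (default: central cones).
#' @return list: `counts` (named integer, zeros included) and `summary`
#'   ([quantity()] with mean, SD, n).
#' @export
convergence <- function(graph, cone_subset = graph$central_cone_ids) {
  if (length(cone_subset) == 0) stop("cone_subset must be non-empty")
  if (!all(cone_subset %in% graph$cone_ids))
    stop("cone_subset must be a subset of the graph's cones")
  tab <- table(factor(graph$edges$cone_id, levels = cone_subset))
  counts <- stats::setNames(as.integer(tab), names(tab))
  s <- if (length(counts) > 1) stats::sd(counts) else 0
  list(counts = counts,
       summary = quantity(mean(counts), s, if (s > 0) "SD" else "none",
                          n = length(counts), units = ""))
}

#' Divergence: cone contacts per rod
#'
#' Counts over contacted rods only (uncontacted rods are tallied by
#' [uncontacted_fraction()]); the histogram bins degrees as 1, 2, 3, 4+.
#'
#' @param graph a [contact_graph()].
#' @param rod_subset rods to consider (default: all rods).
#' @return list: `counts` (named, contacted rods only), `summary`
#'   ([quantity()]), `histogram` (proportions over bins `1`,`2`,`3`,`4+`).
#' @export
divergence <- function(graph, rod_subset = graph$rod_ids) {
  if (length(rod_subset) == 0) stop("rod_subset must be non-empty")
  e <- graph$edges[graph$edges$rod_id %in% rod_subset, ]
  tab <- table(e$rod_id)
  counts <- stats::setNames(as.integer(tab), names(tab))
  if (length(counts) == 0) {
    return(list(counts = counts, summary = quantity(0, units = ""),
                histogram = c(`1` = 0, `2` = 0, `3` = 0, `4+` = 0)))
  }
  bins <- cut(counts, breaks = c(0.5, 1.5, 2.5, 3.5, Inf),
              labels = c("1", "2", "3", "4+"))
  hist <- prop.table(table(bins))
  s <- if (length(counts) > 1) stats::sd(counts) else 0
  list(counts = counts,
       summary = quantity(mean(counts), s, if (s > 0) "SD" else "none",
                          n = length(counts), units = ""),
       histogram = stats::setNames(as.numeric(hist), names(hist)))
}

#' Coverage factor of the telodendrial network
#'
#' Summed field area over region area (the convention under which 29 fields
#' of 104 um^2 in the reconstructed patch give 1.56; overlap is the point, so
#' union area is deliberately not used).
#'
#' @param graph a [contact_graph()].
#' @return dimensionless coverage.
#' @export
coverage <- function(graph) {
  if (is.na(graph$region_area) || graph$region_area <= 0)
    stop("region_area must be positive")
  a <- graph$cone_field_area[graph$cone_ids]
  miss <- graph$cone_ids[is.na(a)]
  if (length(miss))
    stop("missing field area for cone(s): ", paste(miss, collapse = ", "))
  sum(a) / graph$region_area
}

#' Shared and exclusive rod counts
#'
#' `shared[c1, c2]` is the number of rods contacting both cones; `exclusive`
#' counts rods contacting that cone and no other cone *in the whole graph*
#' (annulus cones suppress false exclusivity even when summaries are over the
#' central subset).
#'
#' @param graph a [contact_graph()].
#' @param central_ids cones to report (default: the graph's central set).
#' @return list: `shared` (symmetric matrix, zero diagonal), `exclusive`
#'   (named integer), summaries as [quantity()] objects.
#' @export
shared_and_exclusive <- function(graph, central_ids = graph$central_cone_ids) {
  if (length(central_ids) == 0) stop("central_ids must be non-empty")
  rod_degree <- table(graph$edges$rod_id)
  by_cone <- split(graph$edges$rod_id, graph$edges$cone_id)
  k <- length(central_ids)
  shared <- matrix(0L, k, k, dimnames = list(central_ids, central_ids))
  if (k > 1) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      s <- length(intersect(by_cone[[central_ids[i]]],
                            by_cone[[central_ids[j]]]))
      shared[i, j] <- shared[j, i] <- s
    }
  }
  exclusive <- vapply(central_ids, function(c) {
    rods <- by_cone[[c]]
    if (is.null(rods)) return(0L)
    sum(rod_degree[rods] == 1L)
  }, integer(1))
  pair_vals <- shared[upper.tri(shared)]
  list(
    shared = shared, exclusive = exclusive,
    shared_summary = if (length(pair_vals))
      quantity(mean(pair_vals),
               if (length(pair_vals) > 1) stats::sd(pair_vals) else 0,
               if (length(pair_vals) > 1) "SD" else "none",
               n = length(pair_vals), units = "") else NULL,
    exclusive_summary = quantity(mean(exclusive),
                                 if (k > 1) stats::sd(exclusive) else 0,
                                 if (k > 1) "SD" else "none", n = k,
                                 units = "")
  )
}

#' Fraction of rods without any cone contact
#'
#' @param graph a [contact_graph()].
#' @param rod_subset rods to consider (default: all).
#' @return list `k` (uncontacted), `n` (total), `fraction`, and `percent`
#'   displayed at 1 significant figure as in the source tally (3/811 = 0.4%).
#' @export
uncontacted_fraction <- function(graph, rod_subset = graph$rod_ids) {
  if (length(rod_subset) == 0) stop("rod_subset must be non-empty")
  contacted <- unique(graph$edges$rod_id)
  k <- sum(!rod_subset %in% contacted)
  n <- length(rod_subset)
  list(k = k, n = n, fraction = k / n,
       percent = signif_half_up(100 * k / n, 1))
}

#' Full connectivity report
#'
#' Computes convergence (over central cones), divergence (over all rods and
#' over rods touching a central cone, labeled separately), degree histogram,
#' coverage, shared/exclusive counts, and the uncontacted tally, and asserts
#' edge-count conservation (sum of convergence over all cones = sum of
#' divergence counts = number of edges).
#'
#' @param graph a [contact_graph()].
#' @return list of class `connectivity_report`.
#' @export
connectivity_report <- function(graph) {
  conv_all <- convergence(graph, graph$cone_ids)
  conv_central <- convergence(graph, graph$central_cone_ids)
  div_all <- divergence(graph)
  central_rods <- unique(
    graph$edges$rod_id[graph$edges$cone_id %in% graph$central_cone_ids])
  div_central <- if (length(central_rods)) divergence(graph, central_rods)
                 else div_all
  stopifnot(sum(conv_all$counts) == nrow(graph$edges),
            sum(div_all$counts) == nrow(graph$edges))
  se <- shared_and_exclusive(graph)
  structure(
    list(convergence = conv_central, convergence_all = conv_all,
         divergence_all_rods = div_all,
         divergence_central_rods = div_central,
         coverage = if (!is.na(graph$region_area)) coverage(graph) else NA,
         shared = se$shared, exclusive = se$exclusive,
         shared_summary = se$shared_summary,
         exclusive_summary = se$exclusive_summary,
         uncontacted = uncontacted_fraction(graph),
         n_edges = nrow(graph$edges)),
    class = "connectivity_report"
  )
}

#' @export
print.connectivity_report <- function(x, ...) {
  cat("Rod/cone connectivity report\n")
  cat("  edges:", x$n_edges, "\n")
  cat("  convergence (central cones):",
      format_quantity(x$convergence$summary), "\n")
  cat("  divergence (all rods):",
      format_quantity(x$divergence_all_rods$summary), "\n")
  cat("  divergence (central rods):",
      format_quantity(x$divergence_central_rods$summary), "\n")
  if (!is.na(x$coverage)) cat("  coverage:", signif(x$coverage, 3), "\n")
  cat("  exclusive rods/cone:", format_quantity(x$exclusive_summary), "\n")
  cat("  uncontacted rods:", x$uncontacted$k, "/", x$uncontacted$n,
      paste0("(", x$uncontacted$percent, "%)"), "\n")
  invisible(x)
}
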