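# Expression aggregation: tier censuses, per-superfamily summaries, the
# precursor-count vs read-count regression, and the run report bundle.

#' Ordinary least squares regression of reads on precursor counts
#'
#' Fits reads ~ precursors per superfamily by OLS; a log10-log10 fit is
#' included when all points are positive (the scale of the published
#' regression is not fixed, so both are reported).
#'
#' @param points data.frame with columns \code{n_precursors},
#'   \code{n_reads} (one row per superfamily).
#' @return list with \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{loglog} (or NULL) and the input \code{points}.
#' @export
regress_abundance <- function(points) {
  stopifnot(nrow(points) >= 2)
  if (stats::var(points$n_precursors) == 0) stop("degenerate fit: all x equal")
  r2_of <- function(fit, y) {
    ssr <- sum(stats::residuals(fit)^2)
    sst <- sum((y - mean(y))^2)
    if (sst == 0) 1 else 1 - ssr / sst
  }
  fit <- stats::lm(n_reads ~ n_precursors, data = points)
  r2 <- r2_of(fit, points$n_reads)
  ll <- NULL
  if (all(points$n_precursors > 0) && all(points$n_reads > 0)) {
    lf <- stats::lm(log10(n_reads) ~ log10(n_precursors), data = points)
    ll <- list(slope = unname(stats::coef(lf)[2]),
               intercept = unname(stats::coef(lf)[1]),
               r_squared = r2_of(lf, log10(points$n_reads)))
  }
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2, loglog = ll, points = points)
}

#' Build the run report bundle
#'
#' Aggregates stage outputs into category proportions, per-superfamily
#' precursor/read/tier tables, framework-class, variant-event and
#' selection-zone censuses, with deterministic ordering.
#'
#' @param categories data.frame (\code{id}, \code{category}).
#' @param taxonomy data.frame (\code{precursor_id}, \code{superfamily}).
#' @param tiers data.frame (\code{precursor_id}, \code{read_count},
#'   \code{tier}).
#' @param frameworks data.frame (\code{precursor_id}, \code{pattern_class}).
#' @param events Optional data.frame (\code{kind}).
#' @param selection Optional data.frame (\code{zone}).
#' @return list of class \code{venomics_report}.
#' @export
build_report <- function(categories, taxonomy, tiers, frameworks,
                         events = NULL, selection = NULL) {
  for (nm in c("categories", "taxonomy", "tiers", "frameworks"))
    if (is.null(get(nm))) stop("missing stage output: ", nm)
  cat_tab <- table(categories$category)
  cat_prop <- as.numeric(cat_tab) / sum(cat_tab)
  names(cat_prop) <- names(cat_tab)

  m <- merge(taxonomy, tiers, by = "precursor_id")
  m <- m[order(m$superfamily, m$precursor_id), ]
  sf_split <- split(m, m$superfamily)
  sf_tab <- do.call(rbind, lapply(names(sf_split), function(sf) {
    x <- sf_split[[sf]]
    data.frame(superfamily = sf, n_precursors = nrow(x),
               n_reads = sum(x$read_count),
               n_high = sum(x$tier == "high"), n_low = sum(x$tier == "low"),
               n_rare = sum(x$tier == "rare"), stringsAsFactors = FALSE)
  }))
  sf_tab <- sf_tab[order(sf_tab$superfamily), , drop = FALSE]
  rownames(sf_tab) <- NULL

  tier_census <- c(high = sum(tiers$tier == "high"),
                   low = sum(tiers$tier == "low"),
                   rare = sum(tiers$tier == "rare"))
  fw_census <- table(frameworks$pattern_class)
  ev_census <- if (!is.null(events) && nrow(events)) table(events$kind) else table(character(0))
  sel_census <- if (!is.null(selection) && nrow(selection)) table(selection$zone) else table(character(0))

  regression <- if (nrow(sf_tab) >= 2 && stats::var(sf_tab$n_precursors) > 0)
    regress_abundance(sf_tab[, c("n_precursors", "n_reads")]) else NULL

  structure(list(category_proportions = cat_prop,
                 superfamilies = sf_tab, tier_census = tier_census,
                 framework_census = fw_census, event_census = ev_census,
                 selection_census = sel_census, regression = regression),
            class = "venomics_report")
}

#' @export
print.venomics_report <- function(x, ...) {
  cat("venomics run report\n")
  cat("  transcripts by category:\n")
  for (nm in names(x$category_proportions))
    cat(sprintf("    %-18s %5.1f%%\n", nm, 100 * x$category_proportions[[nm]]))
  cat(sprintf("  precursors: %d (high %d / low %d / rare %d)\n",
              sum(x$tier_census), x$tier_census[["high"]],
              x$tier_census[["low"]], x$tier_census[["rare"]]))
  if (!is.null(x$regression))
    cat(sprintf("  reads ~ precursors per superfamily: r^2 = %.3f\n",
                x$regression$r_squared))
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits \code{report.json} plus \code{superfamilies.tsv} under \code{dir}.
#'
#' @param report A \code{venomics_report}.
#' @param dir Output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  js <- list(category_proportions = as.list(report$category_proportions),
             tier_census = as.list(report$tier_census),
             framework_census = as.list(report$framework_census),
             event_census = as.list(report$event_census),
             selection_census = as.list(report$selection_census),
             regression = if (!is.null(report$regression))
               list(slope = report$regression$slope,
                    intercept = report$regression$intercept,
                    r_squared = report$regression$r_squared) else NULL)
  jsonlite::write_json(js, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  utils::write.table(report$superfamilies, file.path(dir, "superfamilies.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file.path(dir, "report.json"))
}
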