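# Two-stage stratified cluster sampling and the design-based coverage
# estimator: proportional allocation of clusters to strata, a
# deterministic seeded sample draw over a postal-block frame, and the
# share of eligible individuals who used at least one program service.

#' Allocate survey clusters to strata proportionally
#'
#' Largest-remainder (Hamilton) apportionment of clusters between the
#' urban and rural strata, proportional to population, with ties broken
#' toward the larger stratum. Every stratum receives at least one
#' cluster.
#'
#' @param urban_pop,rural_pop Stratum population sizes (> 0).
#' @param n_clusters Total clusters to allocate (>= 2).
#' @return Named integer vector `c(urban = ..., rural = ...)` summing to
#'   `n_clusters`.
#' @examples
#' allocate_clusters(60000, 40000, 25) # 15 urban, 10 rural
#' @export
allocate_clusters <- function(urban_pop, rural_pop, n_clusters) {
  stopifnot(urban_pop > 0, rural_pop > 0)
  if (n_clusters < 2) stop("need at least one cluster per stratum")
  pops <- c(urban = urban_pop, rural = rural_pop)
  quota <- n_clusters * pops / sum(pops)
  base <- floor(quota)
  rem <- quota - base
  left <- n_clusters - sum(base)
  if (left > 0) {
    # largest remainder; ties toward the larger stratum
    ord <- order(-rem, -pops)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  if (any(base == 0)) {
    donor <- which.max(base)
    base[base == 0] <- 1
    base[donor] <- base[donor] - sum(base) + n_clusters
  }
  stats::setNames(as.integer(base), names(pops))
}

#' Survey design for one district
#'
#' @param district District identifier.
#' @param urban_pop,rural_pop Stratum population sizes.
#' @param n_clusters Clusters to draw in the district (default 25).
#' @param families_per_cluster Families per cluster (default 10).
#' @param seed Integer seed; the draw is a pure function of
#'   (frame, design) including this seed.
#' @return An object of class `pen_survey_design`.
#' @export
survey_design <- function(district, urban_pop, rural_pop,
                          n_clusters = 25, families_per_cluster = 10,
                          seed = 1L) {
  out <- list(district = district, urban_pop = urban_pop,
              rural_pop = rural_pop, n_clusters = n_clusters,
              families_per_cluster = families_per_cluster,
              seed = as.integer(seed))
  out$allocation <- allocate_clusters(urban_pop, rural_pop, n_clusters)
  class(out) <- "pen_survey_design"
  out
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the
# caller's RNG state is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Substream seed for cluster k of a master seed: deterministic, and
# independent of how many clusters are drawn, so adding a cluster never
# perturbs earlier ones. Kept within 32-bit integer range.
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647)
}

#' Draw a two-stage stratified cluster sample
#'
#' First stage: within each stratum, the allocated number of postal
#' blocks (clusters) is drawn at random without replacement. Second
#' stage: within each selected block, families are invited in random
#' order until the per-cluster family quota is reached; every eligible
#' member of an invited family becomes a survey record. The draw is
#' deterministic given the design seed, with an independent substream
#' per cluster.
#'
#' @param frame A sampling frame as returned by
#'   [generate_population_and_survey()]: list with `blocks` (block_id,
#'   district, stratum, n_families) and `persons` (district, block_id,
#'   family_id, person_id, eligible_protocols, eligible, used_service).
#' @param design A [survey_design()].
#' @return A data.frame of survey records (class `pen_survey`), columns
#'   `district, cluster_id, stratum, family_id, person_id,
#'   eligible_protocols, used_service`.
#' @export
draw_sample <- function(frame, design) {
  blocks <- frame$blocks[frame$blocks$district == design$district, ]
  if (nrow(blocks) == 0) stop("no blocks in frame for district ",
                              design$district)
  recs <- list()
  cluster_no <- 0L
  for (stratum in c("urban", "rural")) {
    n_sel <- design$allocation[[stratum]]
    sb <- blocks[blocks$stratum == stratum, ]
    if (nrow(sb) < n_sel) {
      stop("stratum '", stratum, "' has ", nrow(sb),
           " blocks; design needs ", n_sel)
    }
    sel <- with_seed(
      substream_seed(design$seed, if (stratum == "urban") 1L else 2L),
      sb$block_id[sample.int(nrow(sb), n_sel)]
    )
    for (b in sel) {
      cluster_no <- cluster_no + 1L
      pers <- frame$persons[frame$persons$block_id == b &
                              frame$persons$district == design$district, ]
      fams <- unique(pers$family_id[pers$eligible])
      if (length(fams) < design$families_per_cluster) {
        stop("block '", b, "' exhausted: only ", length(fams),
             " eligible families; need ", design$families_per_cluster)
      }
      invited <- with_seed(
        substream_seed(design$seed, 100L + cluster_no),
        fams[sample.int(length(fams), design$families_per_cluster)]
      )
      take <- pers[pers$family_id %in% invited & pers$eligible, ]
      if (nrow(take) > 0) {
        recs[[length(recs) + 1L]] <- data.frame(
          district = design$district,
          cluster_id = cluster_no,
          stratum = stratum,
          family_id = take$family_id,
          person_id = take$person_id,
          eligible_protocols = take$eligible_protocols,
          used_service = take$used_service,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  class(out) <- c("pen_survey", "data.frame")
  out
}

#' Read survey records from CSV
#'
#' Schema: `district,cluster_id,stratum,family_id,person_id,`
#' `eligible_protocols,used_service`.
#'
#' @param path Path to the survey CSV.
#' @return A `pen_survey` data.frame.
#' @export
read_survey <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("district", "cluster_id", "stratum", "family_id", "person_id",
            "eligible_protocols", "used_service")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop("survey file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  x$used_service <- as.logical(x$used_service)
  if (any(x$used_service & !nzchar(x$eligible_protocols))) {
    stop("used_service = TRUE requires eligibility for at least one protocol")
  }
  class(x) <- c("pen_survey", "data.frame")
  x
}

#' Estimate program coverage
#'
#' Coverage is the proportion of eligible individuals who used at least
#' one program service: the plain ratio of users to eligible respondents,
#' per the program's definition — no design weights and no
#' finite-population correction. A Hajek-style weighted variant
#' (weights column) is available behind `weighted = TRUE`.
#'
#' @param records A `pen_survey` data.frame; every record is an eligible
#'   individual, with `used_service` logical.
#' @param by Grouping: `"overall"`, `"district"`, or `"stratum"`.
#' @param weighted If `TRUE`, use a `weight` column for a weighted ratio
#'   (off by default; the program's definition is unweighted).
#' @return An object of class `pen_coverage`: data.frame with columns
#'   `group`, `n_eligible`, `n_used`, `coverage_pct` (percent, 2 dp in
#'   print; stored at full precision).
#' @examples
#' rec <- data.frame(district = "A", cluster_id = 1, stratum = "urban",
#'                   family_id = 1, person_id = 1:10,
#'                   eligible_protocols = "NCD_RISK",
#'                   used_service = rep(c(TRUE, FALSE), c(3, 7)))
#' estimate_coverage(rec) # 30%
#' @export
estimate_coverage <- function(records, by = c("overall", "district",
                                              "stratum"),
                              weighted = FALSE) {
  by <- match.arg(by)
  if (nrow(records) == 0) stop("no eligible records to estimate coverage from")
  grp <- switch(by,
    overall = rep("overall", nrow(records)),
    district = records$district,
    stratum = records$stratum
  )
  w <- if (weighted) {
    if (is.null(records$weight)) stop("weighted estimate requires a 'weight' column")
    records$weight
  } else rep(1, nrow(records))
  groups <- unique(grp)
  out <- do.call(rbind, lapply(groups, function(g) {
    sel <- grp == g
    if (!any(sel)) stop("empty group: ", g)
    data.frame(
      group = g,
      n_eligible = sum(sel),
      n_used = sum(records$used_service[sel]),
      coverage_pct = 100 * sum(w[sel] * records$used_service[sel]) /
        sum(w[sel]),
      stringsAsFactors = FALSE
    )
  }))
  class(out) <- c("pen_coverage", "data.frame")
  out
}

#' @export
print.pen_coverage <- function(x, ...) {
  cat("Program coverage (eligible individuals who used >= 1 service)\n")
  y <- as.data.frame(x)
  y$coverage_pct <- sprintf("%.2f%%", y$coverage_pct)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Write coverage estimates to CSV
#'
#' Writes overall, per-district, and per-stratum coverage percentages.
#'
#' @param records A `pen_survey` data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_coverage_csv <- function(records, path) {
  rows <- rbind(
    cbind(level = "overall", as.data.frame(estimate_coverage(records, "overall"))),
    cbind(level = "district", as.data.frame(estimate_coverage(records, "district"))),
    cbind(level = "stratum", as.data.frame(estimate_coverage(records, "stratum")))
  )
  rows$coverage_pct <- round(rows$coverage_pct, 2)
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
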