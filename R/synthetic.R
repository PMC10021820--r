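# Synthetic scenario generator: complete, internally consistent program
# inputs (cost ledger, DOM task-time logs, staffing roster, sampling
# frame, denominators) generated from a scenario configuration with
# closed-form expected outputs, so every pipeline stage is testable
# end-to-end without external data.

#' Construct a synthetic program scenario
#'
#' A scenario fixes the study conditions: two districts with urban/rural
#' strata, annual cost levels per protocol and category, the overhead
#' (non-specific) cost totals, role rosters and true per-visit time
#' scales, survey-frame sizes, the true service-usage probability, and
#' the population denominators. Every generator is a pure function of
#' (scenario, seed).
#'
#' @param districts Named list of districts, each a list with
#'   `urban_pop` and `rural_pop`.
#' @param supply_totals,personnel_totals,equipment_totals Named numeric
#'   vectors over [pen_protocols()]: target annual program-level USD per
#'   category.
#' @param nonspecific Named numeric vector of overhead annual totals:
#'   `consultancy, retraining, supervision_recurrent, introduction,`
#'   `customization, supervision_capital`.
#' @param denominators Data.frame `district, protocol,`
#'   `eligible_population, covered_population`, or `NULL` if per-capita
#'   reporting is not needed.
#' @param usage_prob True probability that an eligible individual used at
#'   least one service (coverage ground truth).
#' @param eligibility Named per-protocol probabilities that a frame
#'   individual is eligible; the NCD risk-factor survey should be 1 (all
#'   adults are in its target population), which also guarantees every
#'   family is interviewable.
#' @param shared_supply_usd Annual USD of one shared supply item (e.g.
#'   disposable gloves) carved out of — and split back equally between —
#'   `shared_supply_protocols`; exercises the shared-item split without
#'   moving category totals.
#' @param shared_supply_protocols Protocols sharing that item.
#' @param time_scale_minutes Per-role total service-minutes scale: the
#'   true mean per-visit time for protocol k is
#'   `time_scale_minutes * s_k` where `s_k` is protocol k's share of the
#'   personnel total, so personnel cost attribution has an analytic
#'   ground truth.
#' @param time_cv Coefficient of variation of per-visit times (lognormal);
#'   0 gives degenerate (exact-mean) times.
#' @param balanced_dom If `TRUE`, the DOM log uses a balanced design (one
#'   observation per site x role x protocol) so realized protocol
#'   minute-shares equal their expectations exactly; if `FALSE`, 10-20
#'   patients per site with uniformly sampled role and protocol.
#' @param visits_per_day Average program visits per provider per day.
#' @param role_share Named fractions splitting the personnel total across
#'   physician/midwife/chw (sums to 1).
#' @param headcounts Named provider headcounts per district-stratum
#'   roster row.
#' @param blocks_per_stratum,families_per_block,members_per_family Survey
#'   frame sizes per district stratum.
#' @param pilot_duration_months Pilot window length (months) used for
#'   supply observation windows.
#' @param equipment_lives Named useful lives (years) for protocols with
#'   equipment.
#' @param constants A [pen_constants()] object.
#' @return An object of class `pen_scenario`.
#' @export
pen_scenario <- function(districts,
                         supply_totals,
                         personnel_totals,
                         equipment_totals,
                         nonspecific,
                         denominators = NULL,
                         usage_prob = 0.40,
                         eligibility = c(MI_STROKE = 0.45, RESPIRATORY = 0.30,
                                         CRC = 0.25, FEMALE_CANCER = 0.35,
                                         NCD_RISK = 1.0),
                         shared_supply_usd = 600,
                         shared_supply_protocols = c("MI_STROKE",
                                                     "FEMALE_CANCER"),
                         time_scale_minutes = 60,
                         time_cv = 0,
                         balanced_dom = TRUE,
                         visits_per_day = 10,
                         role_share = c(physician = 0.45, midwife = 0.30,
                                        chw = 0.25),
                         headcounts = c(physician = 8, midwife = 16,
                                        chw = 24),
                         blocks_per_stratum = c(urban = 18, rural = 13),
                         families_per_block = 12,
                         members_per_family = 2,
                         pilot_duration_months = 13,
                         equipment_lives = c(MI_STROKE = 5, RESPIRATORY = 7,
                                             CRC = 5, FEMALE_CANCER = 4,
                                             NCD_RISK = 5),
                         constants = pen_constants()) {
  protos <- pen_protocols()
  supply_totals <- supply_totals[protos]
  personnel_totals <- personnel_totals[protos]
  equipment_totals <- equipment_totals[protos]
  stopifnot(
    !anyNA(supply_totals), !anyNA(personnel_totals), !anyNA(equipment_totals),
    all(supply_totals >= 0), all(personnel_totals >= 0),
    all(equipment_totals >= 0),
    all(nonspecific >= 0),
    usage_prob >= 0, usage_prob <= 1,
    all(eligibility >= 0), all(eligibility <= 1),
    abs(sum(role_share) - 1) < 1e-9,
    time_cv >= 0, time_scale_minutes > 0,
    pilot_duration_months > 0
  )
  need_ns <- c("consultancy", "retraining", "supervision_recurrent",
               "introduction", "customization", "supervision_capital")
  missing_ns <- setdiff(need_ns, names(nonspecific))
  if (length(missing_ns) > 0) {
    stop("nonspecific totals missing: ", paste(missing_ns, collapse = ", "))
  }
  active <- supply_totals + personnel_totals + equipment_totals > 0
  if (sum(nonspecific) == 0 && any(!active)) {
    stop("protocol(s) with no cost item and no overhead: ",
         paste(protos[!active], collapse = ", "))
  }
  if (any(supply_totals[shared_supply_protocols] <
            shared_supply_usd / length(shared_supply_protocols))) {
    stop("shared supply carve-out exceeds a protocol's supply total")
  }
  out <- list(
    districts = districts,
    supply_totals = supply_totals,
    personnel_totals = personnel_totals,
    equipment_totals = equipment_totals,
    nonspecific = nonspecific[need_ns],
    denominators = denominators,
    usage_prob = usage_prob,
    eligibility = eligibility,
    shared_supply_usd = shared_supply_usd,
    shared_supply_protocols = shared_supply_protocols,
    time_scale_minutes = time_scale_minutes,
    time_cv = time_cv,
    balanced_dom = balanced_dom,
    visits_per_day = visits_per_day,
    role_share = role_share,
    headcounts = headcounts,
    blocks_per_stratum = blocks_per_stratum,
    families_per_block = families_per_block,
    members_per_family = members_per_family,
    pilot_duration_months = pilot_duration_months,
    equipment_lives = equipment_lives,
    constants = constants
  )
  class(out) <- "pen_scenario"
  out
}

#' Read a scenario configuration from YAML
#'
#' Reads a scenario YAML (see `inst/extdata/scenario_published.yaml` for the
#' schema) and constructs a [pen_scenario()].
#'
#' @param path Path to a scenario YAML file.
#' @return A `pen_scenario`.
#' @export
read_scenario_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  num <- function(x) stats::setNames(as.numeric(unlist(x)), names(unlist(x)))
  args <- list(
    districts = cfg$districts,
    supply_totals = num(cfg$supply_totals),
    personnel_totals = num(cfg$personnel_totals),
    equipment_totals = num(cfg$equipment_totals),
    nonspecific = num(cfg$nonspecific)
  )
  if (!is.null(cfg$denominators)) {
    args$denominators <- do.call(rbind, lapply(cfg$denominators, as.data.frame))
  }
  for (f in c("usage_prob", "shared_supply_usd", "time_scale_minutes",
              "time_cv", "balanced_dom", "visits_per_day",
              "families_per_block", "members_per_family",
              "pilot_duration_months")) {
    if (!is.null(cfg[[f]])) args[[f]] <- cfg[[f]]
  }
  for (f in c("eligibility", "role_share", "headcounts",
              "blocks_per_stratum", "equipment_lives")) {
    if (!is.null(cfg[[f]])) args[[f]] <- num(cfg[[f]])
  }
  if (!is.null(cfg$shared_supply_protocols)) {
    args$shared_supply_protocols <- unlist(cfg$shared_supply_protocols)
  }
  if (!is.null(cfg$constants)) {
    args$constants <- do.call(pen_constants, cfg$constants)
  }
  do.call(pen_scenario, args)
}

#' Back-solve population denominators from published per-user totals
#'
#' The per-capita identity for protocol k is
#' \deqn{t_k = V_k / C_k + F_k / E_k}
#' with V the annual variable cost, F the annual fixed cost (without
#' introduction), E the eligible and C the covered population. With the
#' published category costs and per-user protocol totals but unpublished
#' denominators, the system is underdetermined; it is closed by assuming
#' one program-wide coverage ratio \eqn{\rho = C_k / E_k} for every
#' protocol, chosen (by `uniroot`) so that the per-capita introduction
#' components sum to the published gap between the with- and
#' without-introduction program totals. Then
#' \eqn{E_k = (V_k/\rho + F_k) / t_k}.
#'
#' @param variable_by_protocol Annual variable cost per protocol (USD).
#' @param fixed_by_protocol Annual fixed cost per protocol, excluding
#'   introduction (USD).
#' @param introduction_by_protocol Annual introduction cost per protocol
#'   (USD).
#' @param totals_without Published per-user protocol totals, without
#'   introduction.
#' @param introduction_gap Published program-level difference between the
#'   with- and without-introduction totals.
#' @return List with `rho` and `denominators` (data.frame
#'   `protocol, eligible_population, covered_population`, integer
#'   counts).
#' @export
calibrate_denominators <- function(variable_by_protocol,
                                   fixed_by_protocol,
                                   introduction_by_protocol,
                                   totals_without,
                                   introduction_gap) {
  V <- variable_by_protocol; Fk <- fixed_by_protocol
  tk <- totals_without
  stopifnot(length(V) == length(Fk), length(tk) == length(V),
            all(tk > 0), introduction_gap > 0)
  gap <- function(rho) {
    E <- (V / rho + Fk) / tk
    sum(introduction_by_protocol / E) - introduction_gap
  }
  if (gap(1) < 0) {
    stop("published totals unattainable: even full coverage (rho = 1) ",
         "implies a smaller introduction gap than published")
  }
  rho <- stats::uniroot(gap, c(1e-3, 1), tol = 1e-12)$root
  E <- (V / rho + Fk) / tk
  list(
    rho = rho,
    denominators = data.frame(
      protocol = names(V),
      eligible_population = round(E),
      covered_population = round(rho * E),
      row.names = NULL, stringsAsFactors = FALSE
    )
  )
}

#' The published-program calibrated scenario
#'
#' Loads the scenario whose category cost levels are set to the pilot
#' program's published annual totals (the summary-table cells), with
#' degenerate (zero-variance) task times and a balanced observation
#' design, and back-solves the unpublished population denominators with
#' [calibrate_denominators()] from the published per-user protocol
#' totals. Running the full pipeline on data generated from this
#' scenario reproduces the published cost breakdown and program totals.
#'
#' @return A `pen_scenario` with calibrated `denominators`.
#' @export
pen_scenario_published <- function() {
  path <- system.file("extdata", "scenario_published.yaml", package = "pencost")
  sc <- read_scenario_yaml(path)
  cfg <- yaml::read_yaml(path)
  tk <- stats::setNames(as.numeric(unlist(cfg$published_totals_without)),
                        names(unlist(cfg$published_totals_without)))
  tk <- tk[pen_protocols()]
  gap <- cfg$published_total_with - cfg$published_total_without
  V <- sc$supply_totals + sc$personnel_totals
  fixed_common <- sum(sc$nonspecific[c("consultancy", "retraining",
                                       "supervision_recurrent",
                                       "customization",
                                       "supervision_capital")]) / 5
  Fk <- fixed_common + sc$equipment_totals
  cal <- calibrate_denominators(
    variable_by_protocol = V,
    fixed_by_protocol = Fk,
    introduction_by_protocol =
      rep(sc$nonspecific[["introduction"]] / 5, 5),
    totals_without = tk,
    introduction_gap = gap
  )
  den <- cal$denominators
  # split program-level counts across the two districts
  dn <- names(sc$districts)
  half <- function(x) cbind(floor(x / 2), x - floor(x / 2))
  e2 <- half(den$eligible_population); c2 <- half(den$covered_population)
  sc$denominators <- data.frame(
    district = rep(dn, each = nrow(den)),
    protocol = rep(den$protocol, 2),
    eligible_population = c(e2[, 1], e2[, 2]),
    covered_population = c(c2[, 1], c2[, 2]),
    stringsAsFactors = FALSE
  )
  sc$calibration_rho <- cal$rho
  sc
}

#' Generate a synthetic cost ledger
#'
#' Emits the item families of the program's expenditure structure:
#' per-protocol supply items observed over the pilot window (split into
#' two sub-items with a seeded random share), one shared supply item
#' split between its using protocols, equipment items with unit counts,
#' unit costs and useful lives, national-level overhead items (to be
#' divided by the number of universities), a national retraining item
#' (additionally divided by the revision cycle), and district-level
#' introduction spend. All amounts are in IRR so the currency-conversion
#' path is exercised. Deterministic given `seed`; amounts are chosen so
#' the annualized pipeline output equals the scenario's category targets
#' exactly.
#'
#' @param scenario A `pen_scenario`.
#' @param seed Integer seed.
#' @return A `pen_ledger` data.frame.
#' @export
generate_ledger <- function(scenario, seed = 1L) {
  cn <- scenario$constants
  rate <- cn$exchange_rate_irr_per_usd
  pm <- scenario$pilot_duration_months
  dn <- names(scenario$districts)
  protos <- pen_protocols()
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- data.frame(...)

  annual_to_window <- function(usd) usd / 12 * pm        # annual -> window
  shared_each <- scenario$shared_supply_usd /
    length(scenario$shared_supply_protocols)

  splits <- with_seed(substream_seed(seed, 1L),
                      stats::runif(length(protos), 0.3, 0.7))
  names(splits) <- protos
  for (p in protos) {
    spec <- scenario$supply_totals[[p]] -
      if (p %in% scenario$shared_supply_protocols) shared_each else 0
    if (spec <= 0) next
    per_district <- spec / length(dn)
    for (d in dn) {
      a <- per_district * splits[[p]]
      b <- per_district - a
      add(item_id = paste0("SUP-", p, "-", d, "-1"),
          name = paste("supplies", p, "batch 1"), district = d,
          level = "district", category = "recurrent", kind = "supply",
          protocols = p, amount = annual_to_window(a) * rate,
          currency = "IRR", units_purchased = NA, unit_cost = NA,
          useful_life_years = NA, observed_over_months = pm)
      add(item_id = paste0("SUP-", p, "-", d, "-2"),
          name = paste("supplies", p, "batch 2"), district = d,
          level = "district", category = "recurrent", kind = "supply",
          protocols = p, amount = annual_to_window(b) * rate,
          currency = "IRR", units_purchased = NA, unit_cost = NA,
          useful_life_years = NA, observed_over_months = pm)
    }
  }
  if (scenario$shared_supply_usd > 0) {
    per_district <- scenario$shared_supply_usd / length(dn)
    for (d in dn) {
      add(item_id = paste0("SUP-SHARED-", d),
          name = "disposable gloves (shared)", district = d,
          level = "district", category = "recurrent", kind = "supply",
          protocols = paste(scenario$shared_supply_protocols,
                            collapse = ";"),
          amount = annual_to_window(per_district) * rate,
          currency = "IRR", units_purchased = NA, unit_cost = NA,
          useful_life_years = NA, observed_over_months = pm)
    }
  }
  eq_units <- c(MI_STROKE = 4, RESPIRATORY = 2, CRC = 1,
                FEMALE_CANCER = 1, NCD_RISK = 1)
  for (p in protos) {
    target <- scenario$equipment_totals[[p]]
    if (target <= 0) next
    L <- scenario$equipment_lives[[p]]
    af <- annualization_factor(L, cn$discount_rate)
    units <- eq_units[[p]]
    unit_cost_irr <- target * af * rate / units
    add(item_id = paste0("EQP-", p),
        name = paste("equipment", p), district = dn[1],
        level = "district", category = "capital", kind = "equipment",
        protocols = p, amount = units * unit_cost_irr,
        currency = "IRR", units_purchased = units,
        unit_cost = unit_cost_irr, useful_life_years = L,
        observed_over_months = NA)
  }
  ns <- scenario$nonspecific
  national <- function(id, nm, kind, category, annual_usd, cycles = 1) {
    add(item_id = id, name = nm, district = "NATIONAL",
        level = "national", category = category, kind = kind,
        protocols = "NONSPECIFIC",
        amount = annual_usd * cn$n_universities * cycles * rate,
        currency = "IRR", units_purchased = NA, unit_cost = NA,
        useful_life_years = NA, observed_over_months = NA)
  }
  national("CONS-NAT", "initial meetings, workshops and consultancy",
           "consultancy", "capital", ns[["consultancy"]])
  national("RETR-NAT", "retraining and material revision",
           "retraining", "recurrent", ns[["retraining"]],
           cycles = cn$retraining_cycle_years)
  national("SUPV-REC-NAT", "annual meetings, workshops and supervision",
           "supervision", "recurrent", ns[["supervision_recurrent"]])
  national("CUST-NAT", "protocol customization",
           "customization", "capital", ns[["customization"]])
  national("SUPV-CAP-NAT", "initial supervision setup",
           "supervision", "capital", ns[["supervision_capital"]])
  for (d in dn) {
    add(item_id = paste0("INTRO-", d),
        name = "program introduction", district = d,
        level = "district", category = "capital", kind = "introduction",
        protocols = "NONSPECIFIC",
        amount = ns[["introduction"]] / length(dn) * rate,
        currency = "IRR", units_purchased = NA, unit_cost = NA,
        useful_life_years = NA, observed_over_months = NA)
  }
  as_pen_ledger(do.call(rbind, rows))
}

# True mean per-visit minutes for protocol k: time scale x protocol share
# of the personnel total.
true_task_minutes <- function(scenario) {
  s <- scenario$personnel_totals / sum(scenario$personnel_totals)
  scenario$time_scale_minutes * s
}

#' Generate DOM task-time logs and a staffing roster
#'
#' Emulates direct observation at 2 urban and 2 rural sites per
#' district. In the balanced design (`balanced_dom = TRUE`) each site
#' contributes one observation per role x protocol with minutes drawn
#' from the true per-visit time distribution (degenerate when
#' `time_cv = 0`); otherwise each site sees a uniform 10-20 patients with
#' role and protocol sampled uniformly. The staffing roster carries one
#' row per district x stratum x role, with salaries set (in IRR) so the
#' expected annual personnel cost equals the scenario's personnel
#' targets.
#'
#' @param scenario A `pen_scenario`.
#' @param seed Integer seed.
#' @return List with `dom` (observation data.frame) and `staffing`
#'   (roster data.frame with `monthly_salary`/`currency` columns, the CSV
#'   schema of [read_staffing()]).
#' @export
generate_dom_logs <- function(scenario, seed = 1L) {
  cn <- scenario$constants
  dn <- names(scenario$districts)
  protos <- pen_protocols()
  roles <- pen_roles()
  mu <- true_task_minutes(scenario)
  cv <- scenario$time_cv
  draw_minutes <- function(p, n) {
    if (cv == 0) rep(mu[[p]], n) else {
      sdlog <- sqrt(log(1 + cv^2))
      stats::rlnorm(n, meanlog = log(mu[[p]]) - sdlog^2 / 2, sdlog = sdlog)
    }
  }
  rows <- list()
  site_no <- 0L
  for (d in dn) for (stratum in c("urban", "rural")) for (s in 1:2) {
    site_no <- site_no + 1L
    site <- paste0(d, "-", stratum, "-S", s)
    obs <- with_seed(substream_seed(seed, 10L + site_no), {
      if (scenario$balanced_dom) {
        # one observation per role x protocol; minutes depend on protocol
        g <- expand.grid(role = roles, protocol = protos,
                         stringsAsFactors = FALSE)
        g$minutes_per_service <- unlist(Map(draw_minutes, g$protocol, 1))
        g
      } else {
        n <- sample(10:20, 1)
        g <- data.frame(
          role = sample(roles, n, replace = TRUE),
          protocol = sample(protos, n, replace = TRUE),
          stringsAsFactors = FALSE
        )
        g$minutes_per_service <- unlist(Map(draw_minutes, g$protocol, 1))
        g
      }
    })
    obs$district <- d
    obs$site <- site
    obs$stratum <- stratum
    obs$visit_date <- "2016-06-15"
    rows[[length(rows) + 1L]] <- obs[, dom_columns()]
  }
  dom <- do.call(rbind, rows)
  rownames(dom) <- NULL

  # salary per roster row back-solved from the personnel target:
  # fraction = mean task time x visits/day / workday; role total is
  # spread equally over the district x stratum rows.
  mean_minutes <- mean(mu)  # balanced-design mean over protocols
  fraction <- worktime_fraction(mean_minutes, scenario$visits_per_day,
                                cn$workday_minutes)
  n_rows_per_role <- length(dn) * 2
  staffing <- list()
  for (d in dn) for (stratum in c("urban", "rural")) for (role in pen_roles()) {
    role_total <- sum(scenario$personnel_totals) * scenario$role_share[[role]]
    hc <- scenario$headcounts[[role]]
    salary_usd <- role_total / n_rows_per_role / (fraction * 12 * hc)
    staffing[[length(staffing) + 1L]] <- data.frame(
      district = d, stratum = stratum, role = role, headcount = hc,
      monthly_salary = salary_usd * cn$exchange_rate_irr_per_usd,
      currency = "IRR",
      visits_per_day = scenario$visits_per_day,
      workday_minutes = cn$workday_minutes,
      stringsAsFactors = FALSE
    )
  }
  list(dom = dom, staffing = do.call(rbind, staffing))
}

#' Generate a synthetic sampling frame with realized service usage
#'
#' Builds the postal-block frame the household survey samples from:
#' per district and stratum, `blocks_per_stratum` geographic blocks of
#' `families_per_block` families of `members_per_family` individuals.
#' Per-protocol eligibility is Bernoulli with the scenario's eligibility
#' fractions (the NCD risk-factor survey covers all adults, so every
#' family has an eligible member); service usage is Bernoulli with the
#' true coverage probability among the eligible. Deterministic given
#' `seed`.
#'
#' @param scenario A `pen_scenario`.
#' @param seed Integer seed.
#' @return A frame: list with `blocks` and `persons` data.frames (see
#'   [draw_sample()]).
#' @export
generate_population_and_survey <- function(scenario, seed = 1L) {
  protos <- pen_protocols()
  dn <- names(scenario$districts)
  blocks <- list(); persons <- list()
  bidx <- 0L
  for (d in dn) for (stratum in c("urban", "rural")) {
    nb <- scenario$blocks_per_stratum[[stratum]]
    nf <- scenario$families_per_block
    npp <- scenario$members_per_family
    if (nb * nf < 1) stop("frame too small for district ", d)
    bidx <- bidx + 1L
    dat <- with_seed(substream_seed(seed, 1000L + bidx), {
      n <- nb * nf * npp
      elig <- sapply(protos, function(p) {
        if (scenario$eligibility[[p]] >= 1) rep(TRUE, n)
        else stats::runif(n) < scenario$eligibility[[p]]
      })
      eligible <- rowSums(elig) > 0
      used <- eligible & (stats::runif(n) < scenario$usage_prob)
      tags <- apply(elig, 1, function(z) paste(protos[z], collapse = ";"))
      list(elig_tags = tags, eligible = eligible, used = used)
    })
    block_ids <- paste0(d, "-", stratum, "-B", seq_len(nb))
    blocks[[length(blocks) + 1L]] <- data.frame(
      block_id = block_ids, district = d, stratum = stratum,
      n_families = nf, stringsAsFactors = FALSE
    )
    persons[[length(persons) + 1L]] <- data.frame(
      district = d,
      block_id = rep(block_ids, each = nf * npp),
      family_id = paste0(rep(block_ids, each = nf * npp), "-F",
                         rep(rep(seq_len(nf), each = npp), nb)),
      person_id = paste0(d, "-", stratum, "-P",
                         seq_len(nb * nf * npp)),
      stratum = stratum,
      eligible_protocols = dat$elig_tags,
      eligible = dat$eligible,
      used_service = dat$used,
      stringsAsFactors = FALSE
    )
  }
  list(blocks = do.call(rbind, blocks),
       persons = do.call(rbind, persons))
}

#' Closed-form expected pipeline outputs for a scenario
#'
#' The scenario's analytic ground truth, derived by closed-form
#' expectation with no simulation: the protocol x category annual cost
#' matrix (category targets plus equal splits of the overhead totals),
#' category totals and shares, the per-capita report under the
#' scenario's denominators, and the true coverage. Used as the recovery
#' oracle for end-to-end tests: with degenerate noise settings the full
#' pipeline must reproduce these numbers exactly (to floating-point
#' round-off).
#'
#' @param scenario A `pen_scenario`.
#' @return List with `cells`, `column_totals`, `grand_total`, `shares`
#'   (as [category_shares()]), `per_capita`, `protocol_totals_without`,
#'   `protocol_totals_with`, `program_total_without`,
#'   `program_total_with`, `coverage`.
#' @export
expected_outputs <- function(scenario) {
  protos <- pen_protocols()
  cats <- pen_categories()
  cells <- matrix(0, nrow = length(protos), ncol = length(cats),
                  dimnames = list(protos, cats))
  cells[, "supply"] <- scenario$supply_totals
  cells[, "personnel"] <- scenario$personnel_totals
  cells[, "equipment"] <- scenario$equipment_totals
  for (cc in c("consultancy", "retraining", "supervision_recurrent",
               "introduction", "customization", "supervision_capital")) {
    cells[, cc] <- scenario$nonspecific[[cc]] / length(protos)
  }
  bk <- list(cells = cells, column_totals = colSums(cells),
             grand_total = sum(cells),
             cost_class = stats::setNames(
               ifelse(cats %in% c("supply", "personnel"),
                      "variable", "fixed"), cats))
  class(bk) <- "pen_breakdown"
  out <- list(
    cells = cells,
    column_totals = bk$column_totals,
    grand_total = bk$grand_total,
    shares = category_shares(bk),
    coverage = scenario$usage_prob
  )
  if (!is.null(scenario$denominators)) {
    rep <- build_report(bk, scenario$denominators)
    out$per_capita <- rep$per_capita
    out$protocol_totals_without <- stats::setNames(
      rep$totals$total_without_introduction, rep$totals$protocol)
    out$protocol_totals_with <- stats::setNames(
      rep$totals$total_with_introduction, rep$totals$protocol)
    out$program_total_without <- rep$program_total_without
    out$program_total_with <- rep$program_total_with
  }
  out
}

#' Simulate replicate coverage surveys
#'
#' Monte-Carlo check of the coverage estimator: holds the frame's
#' eligibility structure fixed, redraws service usage
#' (Bernoulli with the true coverage probability) and the two-stage
#' cluster sample independently per replicate, and returns the estimate
#' from each replicate. Because usage is independent of sample
#' selection, the estimator's expectation is exactly the true
#' probability.
#'
#' @param scenario A `pen_scenario`.
#' @param n_reps Number of replicate surveys.
#' @param seed Integer master seed; each replicate uses an independent
#'   substream.
#' @param district District to survey (defaults to the scenario's
#'   first).
#' @param n_clusters,families_per_cluster Survey design sizes (defaults
#'   from the scenario constants).
#' @return Numeric vector of `n_reps` coverage estimates (fractions in
#'   [0, 1]).
#' @export
simulate_coverage_surveys <- function(scenario, n_reps = 2000, seed = 1L,
                                      district = names(scenario$districts)[1],
                                      n_clusters =
                                        scenario$constants$clusters_per_district,
                                      families_per_cluster =
                                        scenario$constants$families_per_cluster) {
  frame <- generate_population_and_survey(scenario, seed)
  keep <- frame$persons$district == district
  frame$persons <- frame$persons[keep, ]
  frame$blocks <- frame$blocks[frame$blocks$district == district, ]
  d <- scenario$districts[[district]]
  n_elig <- sum(frame$persons$eligible)
  vapply(seq_len(n_reps), function(r) {
    rs <- substream_seed(seed, 5000L + r)
    frame$persons$used_service <- with_seed(rs, {
      frame$persons$eligible & (stats::runif(nrow(frame$persons)) <
                                  scenario$usage_prob)
    })
    des <- survey_design(district, d$urban_pop, d$rural_pop,
                         n_clusters = n_clusters,
                         families_per_cluster = families_per_cluster,
                         seed = substream_seed(seed, 9000L + r))
    rec <- draw_sample(frame, des)
    estimate_coverage(rec)$coverage_pct / 100
  }, numeric(1))
}
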