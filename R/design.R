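#' Per-breed disease prevalence
#'
#' @param phenos a `phenotype_set` or `cohort_pool` (any data.frame with
#'   `pop` and `status` columns)
#' @return data.frame with columns `pop`, `n`, `cases`, `prevalence`
#' @export
breed_prevalence <- function(phenos) {
  stopifnot(all(c("pop", "status") %in% names(phenos)))
  if (!nrow(phenos)) stop("empty phenotype table")
  n <- table(phenos$pop)
  cs <- tapply(phenos$status, phenos$pop, sum)
  out <- data.frame(pop = names(n), n = as.integer(n),
                    cases = as.integer(cs[names(n)]),
                    stringsAsFactors = FALSE)
  out$prevalence <- out$cases / out$n
  rownames(out) <- NULL
  out
}

# largest-remainder apportionment of `total` over positive weights
largest_remainder <- function(weights, total) {
  if (sum(weights) <= 0) stop("weights must have positive sum")
  q <- weights / sum(weights) * total
  base <- floor(q)
  rem <- total - sum(base)
  if (rem > 0) {
    o <- order(q - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  as.integer(base)
}

sample_quota <- function(ids, k, what, breed) {
  if (length(ids) < k)
    stop("breed '", breed, "' cannot supply ", k, " ", what, " (shortfall ",
         k - length(ids), ")")
  if (length(ids) == k) ids else sample(ids, k)
}

#' Sample a GWAS cohort from the study pool
#'
#' Implements the five cohort designs: `within` (all cases and controls from
#' one breed), `balanced` (equal numbers from every breed), `random` (breed
#' ignored), `semibalanced` (cases from the 20 highest-prevalence breeds in
#' proportion to breed prevalence, controls split equally over those breeds)
#' and `unbalanced` (cases and controls both proportional to prevalence over
#' the 20 highest-prevalence breeds). All designs return equal numbers of
#' cases and controls when `n_controls = n_cases`. Apportionment uses
#' largest-remainder rounding so per-breed counts sum exactly to the totals.
#'
#' @param pool a `cohort_pool`
#' @param kind one of `within`, `balanced`, `random`, `semibalanced`,
#'   `unbalanced`
#' @param n_cases,n_controls cohort sizes
#' @param prevalences per-breed prevalence table ([breed_prevalence()]);
#'   computed from the pool when omitted (pass the full phenotype set's table
#'   to rank breeds by true prevalence)
#' @param breed breed id for `within`; default picks the breed with the most
#'   pool cases among those satisfying both quotas
#' @param n_breeds_used breeds used by semibalanced/unbalanced (default 20)
#' @param seed integer seed
#' @return a `cohort` data.frame (`individual`, `pop`, `status`) with the
#'   design recorded in attributes
#' @export
sample_design <- function(pool, kind = c("within", "balanced", "random",
                                         "semibalanced", "unbalanced"),
                          n_cases, n_controls = n_cases, prevalences = NULL,
                          breed = NULL, n_breeds_used = 20L, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(inherits(pool, "data.frame"), n_cases >= 0, n_controls >= 0)
  set.seed(seed)
  cases <- pool[pool$status == 1L, ]
  controls <- pool[pool$status == 0L, ]
  pick <- function(df, quota) {
    # quota: named per-breed counts
    unlist(lapply(names(quota), function(b) {
      sample_quota(df$individual[df$pop == b], quota[[b]],
                   if (identical(df, cases)) "cases" else "controls", b)
    }), use.names = FALSE)
  }

  if (kind == "random") {
    ids <- c(sample_quota(cases$individual, n_cases, "cases", "<pool>"),
             sample_quota(controls$individual, n_controls, "controls", "<pool>"))
  } else if (kind == "within") {
    if (is.null(breed)) {
      tab_ca <- table(factor(cases$pop, levels = unique(pool$pop)))
      tab_co <- table(factor(controls$pop, levels = unique(pool$pop)))
      ok <- names(tab_ca)[tab_ca >= n_cases & tab_co >= n_controls]
      if (!length(ok))
        stop("no breed holds ", n_cases, " cases and ", n_controls,
             " controls in the pool")
      breed <- ok[which.max(tab_ca[ok])]
    }
    ids <- c(sample_quota(cases$individual[cases$pop == breed], n_cases,
                          "cases", breed),
             sample_quota(controls$individual[controls$pop == breed],
                          n_controls, "controls", breed))
  } else {
    if (is.null(prevalences)) prevalences <- breed_prevalence(pool)
    if (kind == "balanced") {
      breeds <- sort(prevalences$pop)
      wts <- rep(1, length(breeds))
    } else {
      o <- order(prevalences$prevalence, decreasing = TRUE)
      breeds <- prevalences$pop[o][seq_len(min(n_breeds_used,
                                               nrow(prevalences)))]
      wts <- prevalences$prevalence[match(breeds, prevalences$pop)]
      if (kind == "unbalanced" && n_cases != n_controls)
        stop("unbalanced design requires n_cases == n_controls")
    }
    case_quota <- setNames(largest_remainder(wts, n_cases), breeds)
    control_quota <- switch(kind,
      balanced = setNames(largest_remainder(rep(1, length(breeds)),
                                            n_controls), breeds),
      semibalanced = setNames(largest_remainder(rep(1, length(breeds)),
                                                n_controls), breeds),
      unbalanced = case_quota)
    ids <- c(pick(cases, as.list(case_quota)),
             pick(controls, as.list(control_quota)))
  }
  out <- pool[match(ids, pool$individual), ]
  rownames(out) <- NULL
  class(out) <- c("cohort", "data.frame")
  attr(out, "design") <- list(kind = kind, n_cases = n_cases,
                              n_controls = n_controls, breed = breed,
                              seed = seed)
  out
}
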