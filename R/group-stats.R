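the_mw_cache <- new.env(parent = emptyenv())

# Exact null distribution of the rank sum of group A over all
# choose(n, n_a) equally likely assignments of the observed (mid)ranks.
# Memoised on the midrank multiset so repeated tests on tie-free samples
# of the same sizes enumerate only once.
mw_exact_distribution <- function(ranks, n_a) {
  n <- length(ranks)
  key <- paste(n_a, n, paste(signif(sort(ranks), 12), collapse = ","),
               sep = "|")
  hit <- the_mw_cache[[key]]
  if (!is.null(hit)) return(hit)
  m <- min(n_a, n - n_a)
  idx <- utils::combn(n, m)
  sums <- colSums(matrix(ranks[idx], nrow = m))
  if (m != n_a) {
    # enumerated the smaller group; group A's rank sum is the complement
    sums <- sum(ranks) - sums
  }
  u_all <- sums - n_a * (n_a + 1) / 2
  tab <- sort(unique(u_all))
  counts <- tabulate(match(u_all, tab))
  dist <- list(u = tab, cdf = cumsum(counts) / length(u_all),
               total = length(u_all))
  the_mw_cache[[key]] <- dist
  dist
}

mw_tail_probs <- function(dist, u) {
  i_le <- findInterval(u + 1e-9, dist$u)
  p_le <- if (i_le == 0) 0 else dist$cdf[i_le]
  i_lt <- findInterval(u - 1e-9, dist$u)
  p_lt <- if (i_lt == 0) 0 else dist$cdf[i_lt]
  c(p_le = p_le, p_ge = 1 - p_lt)
}

#' Mann-Whitney U test for two independent groups
#'
#' Rank-based two-sample test with midranks for ties. The U statistic is
#' reported for the first group: `U = R_a - n_a (n_a + 1) / 2` with `R_a`
#' the rank sum of `a` in the pooled sample. The two-sided p-value is the
#' doubled smaller exact tail, capped at 1, computed by full enumeration
#' of all `choose(n_a + n_b, n_a)` group assignments of the observed
#' values whenever that count is at most `exact_cap`; otherwise a normal
#' approximation with tie-corrected variance and a 0.5 continuity
#' correction is used.
#'
#' @param a,b numeric vectors of per-specimen feature values.
#' @param method `"auto"` (exact when feasible), `"exact"`, or
#'   `"normal_approx"`.
#' @param exact_cap largest assignment count enumerated exactly.
#' @return An object of class `group_comparison` with fields
#'   `u_statistic`, `p_two_sided`, `n_a`, `n_b`, `method`,
#'   `tie_corrected`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(a, b, method = c("auto", "exact", "normal_approx"),
                         exact_cap = 200000) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  if (anyNA(a) || anyNA(b) || any(!is.finite(c(a, b))))
    stop("values must be finite", call. = FALSE)
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  pooled <- c(a, b)
  r <- rank(pooled) # midranks
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  ties <- any(duplicated(pooled))
  n_assign <- choose(n, n_a)
  if (method == "auto")
    method <- if (n_assign <= exact_cap) "exact" else "normal_approx"
  if (method == "exact" && n_assign > exact_cap)
    stop("exact enumeration over ", format(n_assign, big.mark = ","),
         " assignments exceeds `exact_cap`", call. = FALSE)
  if (method == "exact") {
    dist <- mw_exact_distribution(r, n_a)
    tails <- mw_tail_probs(dist, u)
    p <- min(1, 2 * min(tails))
  } else {
    mu <- n_a * n_b / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- max(0, abs(u - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-z))
    }
  }
  structure(list(u_statistic = u, p_two_sided = p, n_a = n_a, n_b = n_b,
                 method = method, tie_corrected = ties),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n = %d vs %d), two-sided p = %.4g [%s%s]\n",
              x$u_statistic, x$n_a, x$n_b, x$p_two_sided, x$method,
              if (x$tie_corrected) ", ties" else ""))
  invisible(x)
}

#' Check whether replicate sets can be pooled
#'
#' Biopsy sets collected in replicate sessions may only be pooled into one
#' group when they show no distributional difference. For every feature
#' and group this runs pairwise Mann-Whitney tests across the sets;
#' pooling is approved for a feature (within a group) iff no pairwise
#' p-value falls below `alpha`.
#'
#' @param data data.frame with one row per specimen.
#' @param features character vector of feature column names.
#' @param group_col,set_col column names holding the group and set labels.
#' @param alpha pooling significance threshold (default 0.05).
#' @param ... passed on to [mann_whitney()].
#' @return List with `pairwise` (tidy data.frame of all pairwise tests)
#'   and `decision` (one row per group x feature with `pooling_approved`).
#' @export
check_set_poolability <- function(data, features, group_col = "group",
                                  set_col = "set_id", alpha = 0.05, ...) {
  stopifnot(is.data.frame(data), all(features %in% names(data)),
            group_col %in% names(data), set_col %in% names(data))
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)",
                                     call. = FALSE)
  rows <- list()
  for (g in unique(data[[group_col]])) {
    d <- data[data[[group_col]] == g, , drop = FALSE]
    sets <- sort(unique(d[[set_col]]))
    if (length(sets) < 2L)
      stop("group ", g, " has fewer than 2 sets", call. = FALSE)
    for (f in features) {
      pairs <- utils::combn(length(sets), 2L)
      for (j in seq_len(ncol(pairs))) {
        s1 <- sets[pairs[1, j]]; s2 <- sets[pairs[2, j]]
        va <- d[[f]][d[[set_col]] == s1]
        vb <- d[[f]][d[[set_col]] == s2]
        if (length(va) < 2L || length(vb) < 2L)
          stop("each set needs >= 2 specimens", call. = FALSE)
        cmp <- mann_whitney(va, vb, ...)
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, feature = f, set_a = s1, set_b = s2,
          n_a = cmp$n_a, n_b = cmp$n_b, u_statistic = cmp$u_statistic,
          p_two_sided = cmp$p_two_sided, method = cmp$method,
          stringsAsFactors = FALSE)
      }
    }
  }
  pairwise <- do.call(rbind, rows)
  dec <- stats::aggregate(p_two_sided ~ group + feature, data = pairwise,
                          FUN = min)
  names(dec)[names(dec) == "p_two_sided"] <- "min_p"
  dec$pooling_approved <- dec$min_p >= alpha
  list(pairwise = pairwise, decision = dec)
}

validate_procedure_records <- function(records) {
  need <- c("animal_id", "bioptome", "n_manoeuvres", "n_biopsies",
            "major_complication")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(records) == 0L) stop("no procedure records", call. = FALSE)
  if (any(records$n_manoeuvres < 1L))
    stop("each procedure needs at least one cutting manoeuvre",
         call. = FALSE)
  if (any(records$n_biopsies < 0L))
    stop("biopsy counts must be non-negative", call. = FALSE)
  if (any(records$n_biopsies > records$n_manoeuvres))
    stop("n_biopsies cannot exceed n_manoeuvres", call. = FALSE)
  invisible(records)
}

#' Cutting success rate per bioptome
#'
#' Per animal, the cutting success is 100 x acquired biopsies / cutting
#' manoeuvres (a manoeuvre = one open-close attempt at the endocardial
#' wall). Summarised per bioptome as mean and sample (n - 1) SD across
#' animals.
#'
#' @param records data.frame with columns `animal_id`, `bioptome`,
#'   `n_manoeuvres`, `n_biopsies`, `major_complication`.
#' @return data.frame with one row per bioptome: `n_animals`,
#'   `mean_percent`, `sd_percent`.
#' @export
cutting_success <- function(records) {
  validate_procedure_records(records)
  records$rate <- 100 * records$n_biopsies / records$n_manoeuvres
  out <- do.call(rbind, lapply(split(records, records$bioptome), function(d)
    data.frame(bioptome = d$bioptome[1], n_animals = nrow(d),
               mean_percent = mean(d$rate),
               sd_percent = if (nrow(d) > 1L) sd(d$rate) else NA_real_,
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Procedural success per bioptome
#'
#' A procedure succeeds when at least `min_biopsies` biopsies were
#' obtained from the animal without any major complication.
#'
#' @inheritParams cutting_success
#' @param min_biopsies success threshold on the biopsy count (default 6).
#' @return data.frame with one row per bioptome: `n_animals`,
#'   `percent_success`.
#' @export
procedural_success <- function(records, min_biopsies = 6L) {
  validate_procedure_records(records)
  ok <- records$n_biopsies >= min_biopsies & !records$major_complication
  out <- do.call(rbind, lapply(split(seq_len(nrow(records)),
                                     records$bioptome), function(i)
    data.frame(bioptome = records$bioptome[i[1]], n_animals = length(i),
               percent_success = 100 * mean(ok[i]),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Read procedure records from CSV
#'
#' @param path CSV with the [cutting_success()] columns.
#' @return Validated data.frame of procedure records.
#' @export
read_procedure_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  rec$major_complication <- as.logical(rec$major_complication)
  validate_procedure_records(rec)
  rec
}
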