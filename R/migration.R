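# Net migration flows in persons, and the two balancing constraints:
# provincial nets sum to zero nationally, and city nets sum to their
# province, enforced by proportional cutback of the surplus side.

#' Construct a migration-flows object
#'
#' Holds person-count net migration flows by (city, sex, age) and
#' (province, sex, age), before and after balancing.  Usually produced by
#' [flows_from_rates()]; the constructor is exported so small instances can
#' be built directly.
#'
#' @param city_net Tibble with columns `city`, `sex`, `age`, `net`.
#' @param prov_net Tibble with columns `province`, `sex`, `age`, `net`.
#' @param weights Optional tibble `city`, `sex`, `age`, `population` of
#'   previous-year counts, used by [reconcile_cities()] for the additive
#'   fallback when the city sum and provincial target disagree in sign.
#' @return An object of class `migration_flows` with elements `city_net`,
#'   `prov_net`, `city_net_adj` (NULL until reconciled), `prov_net_adj`
#'   (NULL until balanced) and `weights`.
#' @export
migration_flows <- function(city_net, prov_net, weights = NULL) {
  city_net <- tibble::as_tibble(city_net)
  prov_net <- tibble::as_tibble(prov_net)
  structure(list(city_net = city_net, prov_net = prov_net,
                 city_net_adj = NULL, prov_net_adj = NULL,
                 weights = weights),
            class = "migration_flows")
}

#' @export
print.migration_flows <- function(x, ...) {
  cat(sprintf(
    "<migration_flows: %d city rows, %d province rows%s%s>\n",
    nrow(x$city_net), nrow(x$prov_net),
    if (is.null(x$prov_net_adj)) "" else ", provinces balanced",
    if (is.null(x$city_net_adj)) "" else ", cities reconciled"))
  invisible(x)
}

#' Net migration flows from rates and the previous year's population
#'
#' City flows are `previous count x city rate`, elementwise by (city, sex,
#' age).  Provincial flows are `province-summed previous count x province
#' rate` per (sex, age).
#'
#' @param prev A [population_state()] for the previous year.
#' @param rates A [rate_set()], or a list with elements `city_mig` and
#'   `prov_mig` as returned by [migration_rate_at()].
#' @param geo A [geo_hierarchy()].
#' @return A [migration_flows()] (unadjusted), carrying the previous-year
#'   counts as reconciliation weights.
#' @export
flows_from_rates <- function(prev, rates, geo) {
  if (inherits(rates, "rate_set")) {
    rates <- list(city_mig = rates$city_mig, prov_mig = rates$prov_mig)
  }
  pm <- .state_to_mats(prev, geo)
  cm <- .mig_tab_to_mats(rates$city_mig, geo$cities$city, "city")
  pmg <- .mig_tab_to_mats(rates$prov_mig, geo$provinces$province, "province")
  pidx <- .prov_index(geo)
  city_net <- lapply(.SEXES, function(s) pm[[s]] * cm[[s]])
  names(city_net) <- .SEXES
  prov_pop <- lapply(.SEXES, function(s) rowsum(pm[[s]], pidx, reorder = TRUE))
  names(prov_pop) <- .SEXES
  prov_net <- lapply(.SEXES, function(s) {
    m <- prov_pop[[s]] * pmg[[s]]
    rownames(m) <- geo$provinces$province
    m
  })
  names(prov_net) <- .SEXES
  fl <- migration_flows(
    city_net = .sex_mats_to_tab(city_net, "city", "net"),
    prov_net = .sex_mats_to_tab(prov_net, "province", "net"),
    weights = .sex_mats_to_tab(list(M = pm$M, F = pm$F), "city", "population")
  )
  fl
}

# rates table -> per-sex matrices, with a hard error on missing units.
.mig_tab_to_mats <- function(tab, units, unit_col) {
  tab <- tibble::as_tibble(tab)
  miss <- setdiff(units, unique(tab[[unit_col]]))
  if (length(miss)) {
    abort_citypop(sprintf("missing migration rate for %s: %s", unit_col,
                          paste(miss, collapse = ", ")))
  }
  tab$age <- age_to_int(tab$age)
  out <- lapply(.SEXES, function(s) {
    sub <- tab[tab$sex == s, ]
    m <- matrix(0, nrow = length(units), ncol = length(.AGES),
                dimnames = list(units, .AGE_LABELS))
    m[cbind(match(sub[[unit_col]], units), sub$age + 1L)] <- sub$rate
    m
  })
  names(out) <- .SEXES
  out
}

.sex_mats_to_tab <- function(mats, unit_col, value_col) {
  units <- rownames(mats$M)
  out <- tibble::tibble(
    unit = rep(units, times = 2L * length(.AGES)),
    sex = rep(.SEXES, each = length(units) * length(.AGES)),
    age = rep(rep(.AGES, each = length(units)), times = 2L),
    value = c(as.numeric(mats$M), as.numeric(mats$F))
  )
  names(out) <- c(unit_col, "sex", "age", value_col)
  dplyr::arrange(out, .data[[unit_col]], .data$sex, .data$age)
}

# ---- balancing cores (matrix form, one column per independent slice) -------

# Scale the surplus side of each column so it sums to zero; the smaller side
# is untouched.  Exact zero enforced by assigning the float residual to the
# largest-magnitude entry of the column.
.balance_cols <- function(P) {
  pos <- pmax(P, 0)
  neg <- -pmin(P, 0)
  Sp <- colSums(pos)
  Sn <- colSums(neg)
  fpos <- ifelse(Sp > Sn & Sp > 0, Sn / Sp, 1)
  fneg <- ifelse(Sn > Sp & Sn > 0, Sp / Sn, 1)
  adj <- sweep(pos, 2, fpos, `*`) - sweep(neg, 2, fneg, `*`)
  r <- colSums(adj)
  fix <- which(r != 0)
  if (length(fix)) {
    top <- apply(abs(adj[, fix, drop = FALSE]), 2, which.max)
    adj[cbind(top, fix)] <- adj[cbind(top, fix)] - r[fix]
  }
  adj
}

# Reconcile city flows (rows) to balanced provincial targets.  `prov_index`
# maps each city row to its province row in `target`.  Multiplicative T/C
# scaling when the raw city sum C shares the sign of the target T;
# otherwise the discrepancy T - C is spread additively in proportion to the
# previous-year population `W` of each city in that slice.
.reconcile_mats <- function(Cflows, target, prov_index, W) {
  np <- nrow(target)
  grp <- factor(prov_index, levels = seq_len(np))
  Csum <- rowsum(Cflows, grp, reorder = TRUE)
  mult <- (Csum != 0) & (Csum * target > 0)
  fac <- ifelse(mult, target / ifelse(Csum == 0, 1, Csum), 1)
  add <- ifelse(mult, 0, target - Csum)
  Wsum <- rowsum(W, grp, reorder = TRUE)
  bad <- (add != 0) & (Wsum <= 0)
  if (any(bad)) {
    abort_citypop(paste0(
      "cannot redistribute migration: a province has zero population but a ",
      "nonzero migration target in some (sex, age) slice"))
  }
  wnorm <- W / ifelse(Wsum[prov_index, , drop = FALSE] > 0,
                      Wsum[prov_index, , drop = FALSE], 1)
  adj <- Cflows * fac[prov_index, , drop = FALSE] +
    add[prov_index, , drop = FALSE] * wnorm
  # exact per-(province, slice) residual fix
  resid <- target - rowsum(adj, grp, reorder = TRUE)
  for (p in seq_len(np)) {
    rows <- which(prov_index == p)
    cols <- which(resid[p, ] != 0)
    if (!length(cols)) next
    sub <- abs(adj[rows, cols, drop = FALSE])
    top <- rows[apply(sub, 2, which.max)]
    adj[cbind(top, cols)] <- adj[cbind(top, cols)] - resid[p, cols]
  }
  adj
}

# ---- tidy wrappers ----------------------------------------------------------

.flow_tab_to_mats <- function(tab, unit_col, value_col, units = NULL) {
  tab <- tibble::as_tibble(tab)
  tab$age <- age_to_int(tab$age)
  units <- units %||% sort(unique(tab[[unit_col]]))
  sexes <- .SEXES
  out <- lapply(sexes, function(s) {
    sub <- tab[tab$sex == s, ]
    m <- matrix(0, nrow = length(units), ncol = length(.AGES),
                dimnames = list(units, .AGE_LABELS))
    m[cbind(match(sub[[unit_col]], units), sub$age + 1L)] <- sub[[value_col]]
    m
  })
  names(out) <- sexes
  out
}

#' Balance provincial net migration to zero nationally
#'
#' For each (sex, age) slice, let `S+` be the sum of positive provincial
#' nets and `S-` the magnitude of the negative sum.  The side with larger
#' magnitude is scaled by `min(S+, S-) / max(S+, S-)`; the smaller side is
#' unchanged ("proportional cutback of the excess").  The result sums to
#' zero exactly.  Balancing never changes the sign of a flow and never
#' increases its magnitude, and it is idempotent.
#'
#' @param flows A [migration_flows()] with `prov_net` populated.
#' @return The flows object with `prov_net_adj` filled in.
#' @examples
#' fl <- migration_flows(
#'   city_net = data.frame(city = "a", sex = "M", age = 30, net = 0),
#'   prov_net = data.frame(province = c("P1", "P2"), sex = "M", age = 30,
#'                         net = c(30, -10))
#' )
#' balance_provinces(fl)$prov_net_adj$net_adj
#' @export
balance_provinces <- function(flows) {
  stopifnot(inherits(flows, "migration_flows"))
  units <- unique(flows$prov_net$province)
  mats <- .flow_tab_to_mats(flows$prov_net, "province", "net", units)
  adj <- lapply(mats, .balance_cols)
  names(adj) <- .SEXES
  tab <- .sex_mats_to_tab(adj, "province", "net_adj")
  # keep only the slices that were present in the input
  key <- flows$prov_net[c("province", "sex", "age")]
  key$age <- age_to_int(key$age)
  tab <- dplyr::semi_join(tab, key, by = c("province", "sex", "age"))
  flows$prov_net_adj <- tab
  flows
}

#' Reconcile city flows to the balanced provincial totals
#'
#' Within each (province, sex, age): if the raw city sum `C` is nonzero and
#' shares the sign of the provincial target `T`, every city flow is scaled
#' by `T / C`; if `C = 0` or the signs disagree, the discrepancy `T - C`
#' is distributed additively across the province's cities in proportion to
#' their previous-year population of that (sex, age).  Afterwards the city
#' flows of each province sum exactly to its adjusted provincial flow.
#'
#' @param flows A [migration_flows()] with `prov_net_adj` populated (see
#'   [balance_provinces()]) and, if the additive fallback can trigger,
#'   `weights` populated (automatic when built by [flows_from_rates()]).
#' @param geo A [geo_hierarchy()].
#' @return The flows object with `city_net_adj` filled in.
#' @export
reconcile_cities <- function(flows, geo) {
  stopifnot(inherits(flows, "migration_flows"))
  if (is.null(flows$prov_net_adj)) {
    abort_citypop("call balance_provinces() before reconcile_cities()")
  }
  cities <- geo$cities$city
  provs <- geo$provinces$province
  pidx <- .prov_index(geo)
  cmats <- .flow_tab_to_mats(flows$city_net, "city", "net", cities)
  tmats <- .flow_tab_to_mats(flows$prov_net_adj, "province", "net_adj", provs)
  if (!is.null(flows$weights)) {
    wmats <- .flow_tab_to_mats(flows$weights, "city", "population", cities)
  } else {
    # no weights supplied: equal split among the province's cities
    ones <- matrix(1, nrow = length(cities), ncol = length(.AGES),
                   dimnames = list(cities, .AGE_LABELS))
    wmats <- list(M = ones, F = ones)
  }
  adj <- lapply(.SEXES, function(s) {
    .reconcile_mats(cmats[[s]], tmats[[s]], pidx, wmats[[s]])
  })
  names(adj) <- .SEXES
  tab <- .sex_mats_to_tab(adj, "city", "net_adj")
  key <- flows$city_net[c("city", "sex", "age")]
  key$age <- age_to_int(key$age)
  flows$city_net_adj <- dplyr::semi_join(tab, key, by = c("city", "sex", "age"))
  flows
}

#' Compute and fully balance migration flows for one projection year
#'
#' Composition of [flows_from_rates()], [balance_provinces()] and
#' [reconcile_cities()]: provincial flows are computed first and cut back
#' so inter-provincial migration sums to zero, then city flows are
#' reconciled so each province's cities sum to its adjusted flow.
#'
#' @inheritParams flows_from_rates
#' @return A [migration_flows()] with both adjusted components populated.
#' @export
apply_migration_balance <- function(prev, rates, geo) {
  flows_from_rates(prev, rates, geo) |>
    balance_provinces() |>
    reconcile_cities(geo)
}

#' Export migration flows as a tidy audit table
#'
#' @param x A [migration_flows()].
#' @param geo A [geo_hierarchy()] (to attach provinces to cities).
#' @param ... Unused.
#' @return Tibble with `province`, `city`, `sex`, `age`, `net`,
#'   `net_adjusted`.
#' @export
tidy.migration_flows <- function(x, geo = NULL, ...) {
  out <- x$city_net
  if (!is.null(x$city_net_adj)) {
    out <- dplyr::left_join(out, x$city_net_adj, by = c("city", "sex", "age"))
    names(out)[names(out) == "net_adj"] <- "net_adjusted"
  }
  if (!is.null(geo)) {
    out <- dplyr::left_join(out, geo$cities[c("city", "province")], by = "city") |>
      dplyr::relocate("province")
  }
  out
}
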