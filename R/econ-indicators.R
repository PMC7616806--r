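# Monetisation stages: heat-mortality losses via the value of a statistical
# life year, lost earnings from heat-related labour loss, and net
# economy-wide carbon prices.

# one row per country from a panel table (economics columns are constant
# within country; the target year's row is taken when a year is given)
econ_rows <- function(econ, year = NULL) {
  if (!is.null(year) && "year" %in% names(econ)) econ <- econ[econ$year == year, ]
  econ[!duplicated(econ$country), , drop = FALSE]
}

#' Monetised loss from heat-related mortality
#'
#' `loss = YLL * VSLY`; also expressed as a percentage of GDP and as the
#' number of average annual incomes the loss is equivalent to. Countries
#' with zero average income get a missing income-equivalent, not zero.
#'
#' @param yll named numeric: years of life lost per country (e.g.
#'   `yll_by_country` from [heat_attributable_mortality()]).
#' @param econ data.frame with country, vsly, gdp, average_income.
#' @param period label for the output rows.
#' @return an [indicator_table()].
#' @export
monetise_heat_mortality <- function(yll, econ, period = "all") {
  e <- econ_rows(econ)
  d <- data.frame(country = names(yll), yll = as.numeric(yll),
                  stringsAsFactors = FALSE)
  d <- merge(d, e[, c("country", "vsly", "gdp", "average_income")],
             by = "country")
  if (any(d$yll < 0)) stop("YLL must be non-negative")
  d$loss <- d$yll * d$vsly
  d$pct_gdp <- 100 * d$loss / d$gdp
  d$income_eq <- ifelse(d$average_income > 0, d$loss / d$average_income, NA_real_)
  bind_indicators(
    indicator_table("heat_mortality_cost", d$country, period, d$loss, "currency"),
    indicator_table("heat_mortality_cost", "GLOBAL", period, sum(d$loss), "currency"),
    indicator_table("heat_mortality_cost_pct_gdp", d$country, period, d$pct_gdp, "%"),
    indicator_table("heat_mortality_cost_pct_gdp", "GLOBAL", period,
                    100 * sum(d$loss) / sum(d$gdp), "%"),
    indicator_table("heat_mortality_income_equivalents", d$country, period,
                    d$income_eq, "persons"),
    indicator_table("heat_mortality_income_equivalents", "GLOBAL", period,
                    sum(d$income_eq, na.rm = TRUE), "persons")
  )
}

#' Lost earnings from heat-related labour capacity loss
#'
#' `loss_s = hours_lost_s * wage_s` per sector; totals, percentage of GDP
#' and the agricultural share of losses are reported per country and
#' globally. A sector with positive hours but no wage is an error.
#'
#' @param hours_lost data.frame (country, sector, year, hours_lost), e.g.
#'   `by_country_sector` from [labour_hours_lost()].
#' @param econ data.frame with country, gdp and `wage_<sector>` columns.
#' @param year target year.
#' @return an [indicator_table()].
#' @export
lost_earnings <- function(hours_lost, econ, year) {
  h <- hours_lost[hours_lost$year == year, ]
  if (!nrow(h)) stop("no labour-loss rows for the requested year")
  e <- econ_rows(econ, year)
  h$wage_col <- paste0("wage_", h$sector)
  miss <- setdiff(unique(h$wage_col[h$hours_lost > 0]), names(e))
  if (length(miss))
    stop("missing wage for sector(s) with positive hours: ",
         paste(sub("^wage_", "", miss), collapse = ", "))
  h$wage <- mapply(function(co, wc) e[[wc]][match(co, e$country)],
                   h$country, h$wage_col)
  h$loss <- h$hours_lost * h$wage
  tot <- tapply(h$loss, h$country, sum)
  ag <- tapply(h$loss[h$sector == "agriculture"],
               h$country[h$sector == "agriculture"], sum)
  ag <- ag[names(tot)]; ag[is.na(ag)] <- 0
  gdp <- e$gdp[match(names(tot), e$country)]
  by_sector <- tapply(h$loss, h$sector, sum)
  per <- as.character(year)
  bind_indicators(
    indicator_table("labour_loss_earnings", names(tot), per, tot, "currency"),
    indicator_table("labour_loss_earnings", "GLOBAL", per, sum(tot), "currency"),
    indicator_table(paste0("labour_loss_earnings_", names(by_sector)), "GLOBAL",
                    per, by_sector, "currency"),
    indicator_table("labour_loss_pct_gdp", names(tot), per, 100 * tot / gdp, "%"),
    indicator_table("labour_loss_pct_gdp", "GLOBAL", per,
                    100 * sum(tot) / sum(gdp), "%"),
    indicator_table("labour_loss_agriculture_share", names(tot), per,
                    ifelse(tot > 0, ag / tot, NA_real_), "fraction"),
    indicator_table("labour_loss_agriculture_share", "GLOBAL", per,
                    sum(ag) / sum(tot), "fraction")
  )
}

#' Net economy-wide carbon price and revenue
#'
#' `net_revenue = carbon_revenue - fossil_subsidies`;
#' `net_price = net_revenue / co2_emissions`. Net revenue is also expressed
#' relative to current health expenditure (signed), and countries with
#' negative net revenue (a net subsidy to fossil fuels) are flagged and
#' counted per HDI group when one is supplied.
#'
#' @param econ data.frame with country, carbon_revenue, fossil_subsidies,
#'   co2_emissions, health_expenditure and optionally hdi_group.
#' @param year target year label.
#' @return an [indicator_table()].
#' @export
net_carbon_price <- function(econ, year = "all") {
  e <- econ_rows(econ, if (identical(year, "all")) NULL else year)
  if (any(e$co2_emissions <= 0)) stop("co2_emissions must be positive")
  net <- e$carbon_revenue - e$fossil_subsidies
  price <- net / e$co2_emissions
  pct_health <- 100 * net / e$health_expenditure
  per <- as.character(year)
  rows <- list(
    indicator_table("net_carbon_revenue", e$country, per, net, "currency"),
    indicator_table("net_carbon_revenue", "GLOBAL", per, sum(net), "currency"),
    indicator_table("net_carbon_price", e$country, per, price, "currency/tonne"),
    indicator_table("net_carbon_revenue_pct_health", e$country, per,
                    pct_health, "%"),
    indicator_table("net_negative_carbon_price", e$country, per,
                    as.numeric(net < 0), "flag"),
    indicator_table("net_negative_carbon_price_count", "GLOBAL", per,
                    sum(net < 0), "countries")
  )
  if ("hdi_group" %in% names(e)) {
    cnt <- tapply(net < 0, e$hdi_group, sum)
    rows <- c(rows, list(indicator_table("net_negative_carbon_price_count",
                                         names(cnt), per, cnt, "countries")))
  }
  do.call(bind_indicators, rows)
}
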