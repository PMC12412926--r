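#' Published descriptive cross-tabulations of low-risk births
#'
#' The eight characteristic-by-outcome contingency tables of the source
#' cohort of 3,168,273 low-risk births (34,980 with a 5-minute Apgar score
#' of 7 or below), as printed: maternal age, education, race/ethnicity,
#' parity, prenatal care initiation, newborn sex, municipal deprivation
#' quintile (IBP) and Koppen climate zone. Rows are the outcome groups
#' (`low` = Apgar 0-7, `normal` = Apgar 8-10); records missing the
#' characteristic are excluded from the table and reported in the
#' `"missing"` attribute (low, normal). The deprivation table carries a
#' `"drop_for_test"` attribute naming the quintile excluded from the
#' published chi-square for small sample size.
#'
#' @return Named list of 2 x k integer matrices with attributes as above,
#'   plus attribute `"totals"` (low, normal column totals including
#'   missing).
#' @export
table1_fixture <- function() {
  tab <- function(low, normal, levels, missing = c(0L, 0L)) {
    m <- rbind(low = low, normal = normal)
    colnames(m) <- levels
    attr(m, "missing") <- c(low = missing[1L], normal = missing[2L])
    m
  }
  out <- list(
    maternal_age = tab(c(5858, 23764, 5358), c(404187, 2222700, 506400),
                       c("<20y", "20-34y", ">=35y"), c(0L, 6L)),
    education = tab(c(28687, 6194), c(2353730, 768931),
                    c("<12y", ">=12y"), c(99L, 10632L)),
    race = tab(c(17909, 14171, 2451, 152, 59),
               c(1793980, 1114328, 178441, 19117, 4607),
               c("White", "Brown", "Black", "Asian", "Indigenous"),
               c(238L, 22820L)),
    parity = tab(c(19247, 8935, 6303), c(1408894, 1007129, 659598),
                 c("nulliparous", "primiparous", "multiparous"),
                 c(495L, 57672L)),
    prenatal = tab(c(28490, 5155), c(2627835, 425084),
                   c("first_trimester", "delayed"), c(1335L, 80374L)),
    sex = tab(c(19996, 14984), c(1586949, 1546344), c("male", "female")),
    ibp = tab(c(11659, 17682, 5196, 443, 0),
              c(1110639, 1580246, 403342, 39060, 5),
              c("1", "2", "3", "4", "5"), c(0L, 1L)),
    koppen = tab(c(2171, 1482, 6971, 20744, 3320, 292),
                 c(133837, 201809, 651614, 1760430, 351980, 33622),
                 c("Af", "Aw", "Cfa", "Cfb", "Cwa", "Cwb"), c(0L, 1L))
  )
  attr(out$ibp, "drop_for_test") <- "5"
  attr(out, "totals") <- c(low = 34980L, normal = 3133293L)
  out
}

#' Published exclusion-cascade counts
#'
#' The printed record counts of the study inclusion flowchart: 4,166,174
#' registered singleton births, the per-criterion exclusion counts, and the
#' final low-risk sample of 3,168,273 with 34,980 low-Apgar cases. Note the
#' printed per-criterion counts were tallied against the full sample (they
#' overlap), so they do not sum to initial minus final; the percentages and
#' the overall case rate recompute from these counts as printed.
#'
#' @return List with `initial`, `final`, `n_cases` and `exclusions`, a
#'   named vector of printed exclusion counts.
#' @export
flowchart_fixture <- function() {
  list(
    initial = 4166174L,
    final = 3168273L,
    n_cases = 34980L,
    exclusions = c(outside_state = 4575L,
                   missing_apgar5 = 19404L,
                   birthweight_out_of_range = 499493L,
                   gestation_out_of_range = 482706L,
                   congenital_anomaly = 51120L,
                   non_cephalic = 145044L,
                   missing_lowrisk_fields = 96117L)
  )
}
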