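#' ICATUS-2016 major divisions
#'
#' Named character vector mapping the nine ICATUS-2016 major-division
#' identifiers (MD1..MD9) to their short labels as used throughout the
#' package: employment; own production; domestic chores; caregiving; unpaid
#' volunteer work; learning; socializing; leisure; self-care.
#'
#' @return Named character vector of length 9.
#' @export
#' @examples
#' icatus_divisions()
icatus_divisions <- function() {
  c(MD1 = "employment and related activities",
    MD2 = "production of goods for own final use",
    MD3 = "unpaid domestic services for household and family members",
    MD4 = "unpaid caregiving services for household and family members",
    MD5 = "unpaid volunteer, trainee and other unpaid work",
    MD6 = "learning",
    MD7 = "socializing and communication, community participation and religious practice",
    MD8 = "culture, leisure, mass media and sports practices",
    MD9 = "self-care and maintenance")
}

#' Construct an activity catalog
#'
#' An activity catalog defines the coded activity vocabulary: for each code,
#' a label, whether the activity is "simultaneous" (performable concurrently
#' with others and always credited the full timeslot), its ICATUS-2016 major
#' division, and whether it is excluded from time aggregation (e.g.
#' resting/sleeping, study-related interactions).
#'
#' @param code Character vector of unique, non-empty activity codes.
#' @param label Character vector of free-text labels.
#' @param simultaneous Logical vector; `TRUE` for simultaneous activities.
#' @param division Character vector of division identifiers (`"MD1"`..`"MD9"`).
#' @param excluded Logical vector; `TRUE` for activities excluded from
#'   time aggregation (they may still count toward concurrency).
#'
#' @return A data frame of class `"activity_catalog"` with columns
#'   `code`, `label`, `simultaneous`, `division`, `excluded`.
#' @seealso [default_catalog()], [read_catalog()], [write_catalog()]
#' @export
activity_catalog <- function(code, label = code, simultaneous = FALSE,
                             division, excluded = FALSE) {
  n <- length(code)
  cat <- data.frame(code = as.character(code),
                    label = as.character(label),
                    simultaneous = rep_len(as.logical(simultaneous), n),
                    division = as.character(division),
                    excluded = rep_len(as.logical(excluded), n),
                    stringsAsFactors = FALSE)
  validate_catalog(cat)
  class(cat) <- c("activity_catalog", "data.frame")
  cat
}

validate_catalog <- function(cat) {
  if (any(!nzchar(cat$code)) || anyNA(cat$code))
    stop("catalog: activity codes must be non-empty")
  if (anyDuplicated(cat$code))
    stop("catalog: duplicate activity codes: ",
         paste(unique(cat$code[duplicated(cat$code)]), collapse = ", "))
  bad <- setdiff(unique(cat$division), names(icatus_divisions()))
  if (length(bad))
    stop("catalog: unknown division identifiers: ", paste(bad, collapse = ", "))
  if (anyNA(cat$simultaneous) || anyNA(cat$excluded))
    stop("catalog: simultaneous/excluded flags must be TRUE or FALSE")
  invisible(cat)
}

#' Default 44-activity catalog
#'
#' Builds the package's default activity vocabulary: 44 activities for a
#' rural low-income-country women's time-use study, of which exactly four
#' are simultaneous (care of the index child; care of other children or
#' adults; chatting with friends or family; watching TV or listening to the
#' radio). Activities map to seven of the nine ICATUS-2016 major divisions;
#' MD5 (unpaid volunteer work) and MD6 (learning) are representable but
#' empty. "Care of the index child" covers feeding, holding, supervising and
#' playing with the child. Post-harvest processing is mapped to domestic
#' chores (MD3) rather than own production. Resting/sleeping and
#' study-related interactions are flagged `excluded` and do not enter time
#' aggregation.
#'
#' The full activity-to-division mapping is a documented reconstruction and
#' can be overridden by editing the CSV written by [write_catalog()] and
#' reloading it with [read_catalog()].
#'
#' @return An [activity_catalog()] with 44 entries.
#' @export
#' @examples
#' cat44 <- default_catalog()
#' nrow(cat44)              # 44
#' sum(cat44$simultaneous)  # 4
default_catalog <- function() {
  e <- function(code, label, div, sim = FALSE, excl = FALSE)
    data.frame(code = code, label = label, simultaneous = sim,
               division = div, excluded = excl, stringsAsFactors = FALSE)
  rows <- rbind(
    # MD1 employment
    e("paid_farm_labor",        "Paid agricultural labor on another's farm", "MD1"),
    e("paid_nonfarm_work",      "Paid non-farm work",                        "MD1"),
    e("petty_trading",          "Petty trading / selling at market",         "MD1"),
    e("transport_for_pay",      "Providing transport for pay",               "MD1"),
    # MD2 own production (incl. water/firewood collection per ICATUS-2016)
    e("tending_crops",          "Tending crops on own plot",                 "MD2"),
    e("weeding",                "Weeding own garden",                        "MD2"),
    e("harvesting",             "Harvesting own crops",                      "MD2"),
    e("tending_livestock",      "Tending livestock and poultry",             "MD2"),
    e("fetching_water",         "Fetching water",                            "MD2"),
    e("collecting_firewood",    "Collecting firewood",                       "MD2"),
    e("home_construction",      "Building or repairing own dwelling",        "MD2"),
    e("making_household_goods", "Making goods for household use (mats, baskets)", "MD2"),
    # MD3 domestic chores (post-harvest processing remapped here)
    e("cooking",                "Cooking",                                   "MD3"),
    e("food_preparation",       "Food preparation",                          "MD3"),
    e("serving_food",           "Serving food",                              "MD3"),
    e("washing_dishes",         "Washing dishes",                            "MD3"),
    e("washing_clothes",        "Washing clothes",                           "MD3"),
    e("cleaning_house",         "Cleaning the house",                        "MD3"),
    e("sweeping_compound",      "Sweeping the compound",                     "MD3"),
    e("post_harvest_processing","Post-harvest processing (shelling, pounding, peeling)", "MD3"),
    e("household_shopping",     "Shopping for the household",                "MD3"),
    e("household_management",   "Household organization and storage",        "MD3"),
    # MD4 caregiving
    e("care_index_child",       "Care of the index child (feeding, holding, supervising, playing)",
      "MD4", sim = TRUE),
    e("care_other_members",     "Care of other children or adults",          "MD4", sim = TRUE),
    e("bathing_child",          "Bathing a child",                           "MD4"),
    e("preparing_child_food",   "Preparing special food for a child",        "MD4"),
    e("child_health_visit",     "Taking a child to a clinic or health visit","MD4"),
    e("soothing_child",         "Soothing a child to sleep",                 "MD4"),
    e("care_sick_member",       "Caring for a sick household member",        "MD4"),
    # MD7 socializing
    e("chatting",               "Chatting with friends or family",           "MD7", sim = TRUE),
    e("visiting_neighbors",     "Visiting neighbors or relatives",           "MD7"),
    e("community_meeting",      "Attending a community meeting",             "MD7"),
    e("religious_practice",     "Religious practice",                        "MD7"),
    e("ceremony_attendance",    "Attending a ceremony (wedding, funeral)",   "MD7"),
    e("personal_phone_call",    "Personal phone call",                       "MD7"),
    # MD8 leisure
    e("tv_radio",               "Watching TV or listening to the radio",     "MD8", sim = TRUE),
    e("playing_games",          "Playing games",                             "MD8"),
    e("sports_recreation",      "Sports and recreation",                     "MD8"),
    # MD9 self-care (resting/sleeping and study interactions excluded)
    e("eating_meal",            "Eating a meal",                             "MD9"),
    e("snacking",               "Snacking",                                  "MD9"),
    e("bathing_self",           "Bathing and personal hygiene",              "MD9"),
    e("grooming_dressing",      "Grooming and dressing",                     "MD9"),
    e("resting_sleeping",       "Resting or sleeping",                       "MD9", excl = TRUE),
    e("study_interaction",      "Study-related interaction (interview, study phone call)",
      "MD9", excl = TRUE)
  )
  activity_catalog(rows$code, rows$label, rows$simultaneous,
                   rows$division, rows$excluded)
}

#' @export
print.activity_catalog <- function(x, ...) {
  cat(sprintf("Activity catalog: %d activities (%d simultaneous, %d excluded from aggregation)\n",
              nrow(x), sum(x$simultaneous), sum(x$excluded)))
  tab <- table(factor(x$division, levels = names(icatus_divisions())))
  cat("Activities per division:\n")
  print(tab)
  invisible(x)
}

#' Read / write an activity catalog as CSV
#'
#' The on-disk form has columns `code,label,simultaneous,division,excluded`
#' with 0/1 flags, so the default catalog can be exported, edited (e.g. to
#' supply a study-specific activity-to-division mapping) and reloaded.
#'
#' @param path Path to a catalog CSV file.
#' @return `read_catalog()` returns an [activity_catalog()];
#'   `write_catalog()` invisibly returns `path`.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path))
    stop("catalog file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("code", "label", "simultaneous", "division", "excluded")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("catalog file ", path, " missing columns: ", paste(miss, collapse = ", "))
  activity_catalog(df$code, df$label,
                   as.integer(df$simultaneous) > 0,
                   df$division,
                   as.integer(df$excluded) > 0)
}

#' @rdname read_catalog
#' @param catalog An [activity_catalog()].
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "activity_catalog"))
  out <- data.frame(code = catalog$code, label = catalog$label,
                    simultaneous = as.integer(catalog$simultaneous),
                    division = catalog$division,
                    excluded = as.integer(catalog$excluded))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
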