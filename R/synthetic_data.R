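#' Configuration for the synthetic dirty-data generator
#'
#' The generator emulates probabilistic dirty-data generation for
#' de-duplication benchmarks: clean "original" person records are drawn from
#' built-in value pools, then "duplicate" records are derived from randomly
#' chosen originals by applying a bounded number of single-character edits
#' (or field clears) to their attributes, and named so that the true entity
#' partition is recoverable (`rec-<k>-org` / `rec-<k>-dup-<j>`).
#'
#' @param n_original number of original records
#' @param n_duplicates number of duplicate records
#'   (`<= n_original * max_dups_per_original`)
#' @param max_dups_per_original cap on duplicates derived from one original
#' @param max_mods_per_duplicate cap on total modifications applied to one
#'   duplicate (each duplicate receives at least 1)
#' @param max_mods_per_attribute cap on modifications hitting the same
#'   attribute of one duplicate
#' @param operators modification operators to draw from, a subset of
#'   `char_insert`, `char_delete`, `char_substitute`, `char_transpose`,
#'   `field_clear`
#' @param seed integer seed; the same configuration and seed give
#'   byte-identical output
#' @return a `generator_config` object
#' @export
generator_config <- function(n_original,
                             n_duplicates,
                             max_dups_per_original = 1L,
                             max_mods_per_duplicate = 1L,
                             max_mods_per_attribute = 1L,
                             operators = c("char_insert", "char_delete",
                                           "char_substitute",
                                           "char_transpose", "field_clear"),
                             seed = 1L) {
  operators <- match.arg(operators, several.ok = TRUE)
  stopifnot(n_original >= 1, n_duplicates >= 0)
  if (n_duplicates > n_original * max_dups_per_original)
    stop("config error: n_duplicates exceeds n_original * ",
         "max_dups_per_original")
  if (n_duplicates > 0L)
    stopifnot(max_dups_per_original >= 1, max_mods_per_duplicate >= 1,
              max_mods_per_attribute >= 1, length(operators) >= 1L)
  structure(list(n_original = as.integer(n_original),
                 n_duplicates = as.integer(n_duplicates),
                 max_dups_per_original = as.integer(max_dups_per_original),
                 max_mods_per_duplicate = as.integer(max_mods_per_duplicate),
                 max_mods_per_attribute =
                   as.integer(max_mods_per_attribute),
                 operators = operators, seed = as.integer(seed)),
            class = "generator_config")
}

#' Built-in benchmark profiles
#'
#' * Profile `"A"` — a *dirty* dataset: 500 originals + 500 duplicates, one
#'   duplicate per original, exactly one modification per duplicate, at most
#'   one modification per attribute (500 true matching pairs).
#' * Profile `"C"` — a *massively dirty* dataset: 600 originals + 400
#'   duplicates, up to nine duplicates per original, up to ten modifications
#'   per duplicate, at most three per attribute.
#'
#' @param profile `"A"` or `"C"`
#' @param seed integer seed
#' @return a [generator_config]
#' @export
dataset_profile <- function(profile = c("A", "C"), seed = 1L) {
  profile <- match.arg(profile)
  switch(profile,
         A = generator_config(500L, 500L, 1L, 1L, 1L, seed = seed),
         C = generator_config(600L, 400L, 9L, 10L, 3L, seed = seed))
}

# ---- value pools ------------------------------------------------------------

pool_given_names <- c(
  "james", "john", "robert", "michael", "william", "david", "richard",
  "joseph", "thomas", "charles", "peter", "daniel", "matthew", "anthony",
  "mark", "paul", "steven", "andrew", "kenneth", "joshua", "kevin", "brian",
  "george", "edward", "ronald", "timothy", "jason", "jeffrey", "ryan",
  "jacob", "gary", "nicholas", "eric", "jonathan", "stephen", "larry",
  "justin", "scott", "brandon", "benjamin", "samuel", "gregory", "frank",
  "alexander", "raymond", "patrick", "jack", "dennis", "jerry", "tyler",
  "mary", "patricia", "jennifer", "linda", "elizabeth", "barbara", "susan",
  "jessica", "sarah", "karen", "nancy", "lisa", "betty", "margaret",
  "sandra", "ashley", "kimberly", "emily", "donna", "michelle", "dorothy",
  "carol", "amanda", "melissa", "deborah", "stephanie", "rebecca", "sharon",
  "laura", "cynthia", "kathleen", "amy", "shirley", "angela", "helen",
  "anna", "brenda", "pamela", "nicole", "emma", "samantha", "katherine",
  "christine", "debra", "rachel", "catherine", "carolyn", "janet", "ruth",
  "maria", "heather", "diane", "virginia", "julie", "joyce", "victoria",
  "olivia", "kelly", "christina", "lauren", "joan", "evelyn", "judith",
  "megan", "cheryl", "hannah", "jacqueline", "martha", "gloria", "teresa")

pool_surnames <- c(
  "smith", "jones", "williams", "brown", "wilson", "taylor", "johnson",
  "white", "martin", "anderson", "thompson", "nguyen", "thomas", "walker",
  "harris", "lee", "ryan", "robinson", "kelly", "king", "davis", "wright",
  "evans", "roberts", "green", "hall", "wood", "jackson", "clarke",
  "patel", "khan", "lewis", "james", "phillips", "mason", "mitchell",
  "rose", "davies", "rodriguez", "cox", "alexander", "garden", "campbell",
  "johnston", "moore", "smyth", "oneill", "doyle", "mccarthy", "gallagher",
  "odonnell", "fitzgerald", "brennan", "salmon", "murray", "quinn",
  "murphy", "mclean", "graham", "watson", "bell", "gordon", "duncan",
  "hunt", "hughes", "bailey", "millar", "morrison", "buchanan", "mitchel",
  "gibson", "muir", "wallace", "ferguson", "hamilton", "stewart", "grant",
  "henderson", "simpson", "mackenzie", "webb", "reid", "fraser", "munro",
  "dunn", "black", "ross", "kerr", "boyd", "craig", "docherty", "sharp",
  "ullman", "hernandez", "stolfo", "christen", "winkler", "fellegi",
  "sunter", "newcombe", "baxter", "gomatam", "clark", "sutton", "howard",
  "turner", "parker", "collins", "edwards", "morris", "cook", "rogers",
  "reed", "baker", "cooper", "richardson", "ward", "peterson", "gray",
  "ramirez", "watts", "brooks", "price", "bennett", "barnes", "wooden",
  "sanders", "long", "foster", "perry", "powell", "hendersen", "russell")

pool_street_names <- c(
  "wattle", "banksia", "acacia", "boronia", "grevillea", "kurrajong",
  "melaleuca", "jacaranda", "eucalypt", "waratah", "george", "william",
  "market", "bridge", "church", "station", "railway", "victoria", "albert",
  "edward", "park", "lake", "river", "hill", "forest", "spring", "summer",
  "autumn", "winter", "north", "south", "east", "west", "high", "main",
  "queen", "kings", "short", "lonsdale", "broad", "greenhill", "stone", "mill",
  "windsor", "oxford", "cambridge", "carlton", "chapel", "crown", "derby",
  "dorset", "essex", "fleet", "gladstone", "hampton", "kent", "lincoln",
  "norfolk", "rowan", "stanley", "sussex", "warwick", "york")

pool_street_types <- c("street", "road", "avenue", "place", "crescent",
                       "drive", "court", "lane", "parade", "terrace")

pool_unit_types <- c("unit", "flat", "apartment", "suite", "villa")

pool_suburbs <- c(
  "richmond", "newtown", "springfield", "lakeside", "brighton", "fairfield",
  "kingston", "clayton", "epping", "carlingford", "fitzroy", "preston",
  "coburg", "brunswick", "essendon", "footscray", "sunshine", "werribee",
  "dandenong", "frankston", "parramatta", "blacktown", "penrith",
  "liverpool", "bankstown", "hornsby", "chatswood", "ryde", "mosman",
  "manly", "bondi", "randwick", "maroubra", "cronulla", "hurstville",
  "auburn", "granville", "ashfield", "burwood", "strathfield", "toowong",
  "indooroopilly", "chermside", "nundah", "wynnum", "capalaba", "ipswich",
  "logan", "redcliffe", "caboolture", "southport", "nerang", "robina",
  "mermaid", "burleigh", "subiaco", "fremantle", "joondalup", "morley",
  "cannington", "armadale", "rockingham", "mandurah", "glenelg", "norwood",
  "unley", "prospect", "salisbury", "elizabeth", "gawler", "marion",
  "sandy bay", "glenorchy", "kingsmeadow", "burnie", "devonport", "belconnen",
  "woden", "tuggeranong", "gungahlin", "palmerston")

pool_states <- c("nsw", "vic", "qld", "wa", "sa", "tas", "act", "nt")

# ---- generation -------------------------------------------------------------

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

random_original <- function() {
  dob_year <- sample(1915:2000, 1L)
  c(given_name = sample(pool_given_names, 1L),
    surname = sample(pool_surnames, 1L),
    street_number = as.character(sample(1:480, 1L)),
    address_1 = paste(sample(pool_street_names, 1L),
                      sample(pool_street_types, 1L)),
    address_2 = if (stats::runif(1) < 0.3)
      paste(sample(pool_unit_types, 1L), sample(1:60, 1L)) else "",
    suburb = sample(pool_suburbs, 1L),
    postcode = sprintf("%04d", sample(2000:7999, 1L)),
    state = sample(pool_states, 1L),
    date_of_birth = sprintf("%04d%02d%02d", dob_year, sample(1:12, 1L),
                            sample(1:28, 1L)),
    age = as.character(sample(18:95, 1L)),
    phone_number = sprintf("0%d %08d", sample(2:8, 1L),
                           sample(10000000:99999999, 1L)),
    soc_sec_id = sprintf("%07d", sample(1000000:9999999, 1L)))
}

#' Apply one modification operator to a field value
#'
#' Single character-level edit at a uniformly chosen position, drawn from
#' the session RNG (seed it for reproducibility): `char_insert` inserts one
#' character, `char_delete` removes one, `char_substitute` replaces one with
#' a different character, `char_transpose` swaps two adjacent characters and
#' `field_clear` empties the value. The insert/substitute alphabet is
#' lowercase letters when the value contains a letter, digits otherwise.
#'
#' @param value character scalar; must be non-empty for delete, substitute
#'   and transpose
#' @param op operator name (see above)
#' @param pos optional 1-based position (the first character affected);
#'   drawn uniformly when `NULL`
#' @return the corrupted value
#' @examples
#' corrupt_value("peter", "char_delete", pos = 3)     # "peer"
#' corrupt_value("peter", "char_transpose", pos = 1)  # "epter"
#' @export
corrupt_value <- function(value, op = c("char_insert", "char_delete",
                                        "char_substitute", "char_transpose",
                                        "field_clear"),
                          pos = NULL) {
  op <- match.arg(op)
  value <- as.character(value)
  n <- nchar(value)
  if (op == "field_clear") return("")
  if (op != "char_insert" && n == 0L)
    stop("config error: ", op, " needs a non-empty value")
  alphabet <- if (grepl("[a-z]", value) || n == 0L) letters
              else as.character(0:9)
  switch(op,
    char_insert = {
      p <- if (is.null(pos)) sample(0:n, 1L) else pos - 1L  # insert after p
      paste0(substr(value, 1L, p), sample(alphabet, 1L),
             substr(value, p + 1L, n))
    },
    char_delete = {
      p <- if (is.null(pos)) sample(n, 1L) else pos
      paste0(substr(value, 1L, p - 1L), substr(value, p + 1L, n))
    },
    char_substitute = {
      p <- if (is.null(pos)) sample(n, 1L) else pos
      old <- substr(value, p, p)
      repl <- sample(setdiff(alphabet, old), 1L)
      paste0(substr(value, 1L, p - 1L), repl, substr(value, p + 1L, n))
    },
    char_transpose = {
      if (n < 2L) return(value)
      p <- if (is.null(pos)) sample(n - 1L, 1L) else pos
      paste0(substr(value, 1L, p - 1L), substr(value, p + 1L, p + 1L),
             substr(value, p, p), substr(value, p + 2L, n))
    })
}

# allocate cfg$n_duplicates over originals, at most max each, >= 1 where used
allocate_duplicates <- function(cfg) {
  counts <- integer(cfg$n_original)
  order_ix <- sample(cfg$n_original)
  left <- cfg$n_duplicates
  for (k in order_ix) {
    if (left == 0L) break
    take <- min(sample(cfg$max_dups_per_original, 1L), left)
    counts[k] <- take
    left <- left - take
  }
  counts
}

make_duplicate <- function(values, cfg) {
  # edits can cancel out (insert then delete); re-draw until the duplicate
  # actually differs from its original
  for (attempt in 1:25) {
    out <- make_duplicate_once(values, cfg)
    if (!identical(out, values)) return(out)
  }
  stop("config error: could not produce a modified duplicate")
}

make_duplicate_once <- function(values, cfg) {
  n_mods <- if (cfg$max_mods_per_duplicate == 1L) 1L
            else sample(cfg$max_mods_per_duplicate, 1L)
  mods_per_attr <- integer(length(values))
  names(mods_per_attr) <- names(values)
  applied <- 0L
  for (m in seq_len(n_mods)) {
    eligible <- names(values)[nzchar(values) &
                                mods_per_attr < cfg$max_mods_per_attribute]
    if (length(eligible) == 0L) break
    f <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
    ops <- cfg$operators
    if (!nzchar(values[[f]]))
      ops <- intersect(ops, "char_insert")
    op <- if (length(ops) == 1L) ops else sample(ops, 1L)
    values[[f]] <- corrupt_value(values[[f]], op)
    mods_per_attr[[f]] <- mods_per_attr[[f]] + 1L
    applied <- applied + 1L
  }
  if (applied == 0L)
    stop("config error: could not apply any modification (all fields empty?)")
  values
}

#' Generate a synthetic dirty dataset with its gold standard
#'
#' Draws `n_original` clean person records from the built-in value pools,
#' then derives `n_duplicates` corrupted copies per the configuration (see
#' [generator_config()]). Records are shuffled so originals and duplicates
#' are interleaved. The same configuration and seed always produce identical
#' output.
#'
#' @param cfg a [generator_config]
#' @return list with `dataset` (a `dedup_dataset`) and `gold`
#'   (a `gold_standard`)
#' @examples
#' out <- generate_dataset(generator_config(50, 50, seed = 7))
#' nrow(out$dataset)                    # 100
#' n_pairs(out$gold$true_match_pairs)   # 50
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  schema <- febrl_schema()
  with_seed(cfg$seed, {
    originals <- lapply(seq_len(cfg$n_original), function(k) random_original())
    counts <- allocate_duplicates(cfg)
    rows <- vector("list", cfg$n_original + cfg$n_duplicates)
    ids <- character(cfg$n_original + cfg$n_duplicates)
    r <- 0L
    for (k in seq_len(cfg$n_original)) {
      r <- r + 1L
      rows[[r]] <- originals[[k]]
      ids[r] <- sprintf("rec-%d-org", k - 1L)
      if (counts[k] > 0L) {
        for (j in seq_len(counts[k])) {
          r <- r + 1L
          rows[[r]] <- make_duplicate(originals[[k]], cfg)
          ids[r] <- sprintf("rec-%d-dup-%d", k - 1L, j - 1L)
        }
      }
    }
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(df) <- schema
    df$rec_id <- ids
    df <- df[sample(nrow(df)), , drop = FALSE]
    ds <- new_dataset(df, schema)
    list(dataset = ds, gold = derive_gold_standard(ds))
  })
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    "generator_config: %d originals + %d duplicates (max %d/original, max %d mods/duplicate, max %d/attribute), seed %d\n",
    x$n_original, x$n_duplicates, x$max_dups_per_original,
    x$max_mods_per_duplicate, x$max_mods_per_attribute, x$seed))
  invisible(x)
}
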