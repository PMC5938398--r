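status_header <- "record_id,plant_id,genus,species,latitude,longitude,date,phenophase_code,status,intensity_lower,intensity_upper"
event_header <- "record_id,plant_or_station_id,genus,species,latitude,longitude,year,event_code,day_of_year"

test_that("well-formed dialect files parse without rejects", {
  sf <- write_lines_tmp(c(
    status_header,
    "S1,p1,Acer,rubrum,45.0,-93.0,2015-04-01,leaves,yes,10,20",
    "S2,p1,Acer,rubrum,45.0,-93.0,2015-04-08,leaves,no,,",
    "S3,p2,Acer,rubrum,44.0,-92.0,2015-04-01,leaves,unknown,,"
  ))
  parsed <- read_status_csv(sf)
  expect_equal(nrow(parsed$records), 3)
  expect_equal(nrow(parsed$rejects), 0)

  ef <- write_lines_tmp(c(
    event_header,
    "E1,st1,Quercus,robur,48.2,16.4,2015,BBCH11,110"
  ))
  pe <- read_event_csv(ef)
  expect_equal(nrow(pe$records), 1)
  expect_equal(pe$records$day_of_year, 110L)
})

test_that("malformed rows are rejected with reasons, not exceptions", {
  ef <- write_lines_tmp(c(
    event_header,
    "E1,st1,Quercus,robur,48.2,16.4,2015,BBCH11,400",
    "E2,st1,Quercus,robur,48.2,16.4,2016,BBCH11,366",
    "E3,st1,Quercus,robur,48.2,16.4,2015,BBCH11,366"
  ))
  pe <- read_event_csv(ef)
  # 2016 is a leap year so day 366 is valid there but not in 2015
  expect_equal(pe$rejects$record_id, c("E1", "E3"))
  expect_equal(pe$rejects$reason, rep("day_of_year outside year", 2))
  expect_equal(pe$records$record_id, "E2")

  sf <- write_lines_tmp(c(
    status_header,
    "S1,p1,Acer,,45.0,-93.0,not-a-date,leaves,yes,,",
    "S2,p1,Acer,,45.0,-93.0,2015-04-01,leaves,maybe,,",
    "S3,p1,Acer,,45.0,-93.0,2015-04-01,leaves,unknown,5,10",
    "S4,p1,Acer,,145.0,-93.0,2015-04-01,leaves,yes,,"
  ))
  ps <- read_status_csv(sf)
  expect_equal(nrow(ps$records), 0)
  expect_equal(nrow(ps$rejects), 4)

  expect_error(read_status_csv(write_lines_tmp("record_id,plant_id")),
               class = "phenokit_schema_error")
})

test_that("parsing conserves rows: records + rejects = input lines", {
  set.seed(41)
  for (rep in 1:10) {
    n <- 50
    good <- runif(n) > 0.3
    lines <- vapply(seq_len(n), function(i) {
      if (good[i]) {
        sprintf("E%03d,st1,Acer,,%.2f,%.2f,%d,BBCH11,%d", i,
                runif(1, 40, 60), runif(1, -10, 30),
                sample(2000:2010, 1), sample(1:365, 1))
      } else {
        sprintf("E%03d,st1,Acer,,45.0,10.0,2015,BBCH11,%d", i,
                sample(367:500, 1))
      }
    }, character(1))
    pe <- read_event_csv(write_lines_tmp(c(event_header, lines)))
    expect_equal(nrow(pe$records) + nrow(pe$rejects), n)
    expect_equal(nrow(pe$records), sum(good))
  }
})

test_that("status semantics map to the documented measurement ranges", {
  catalog <- default_catalog()
  mapping <- default_mapping(catalog)
  sf <- write_lines_tmp(c(
    status_header,
    "S1,p1,Acer,rubrum,45.0,-93.0,2015-04-01,leaves,yes,10,20",
    "S2,p1,Acer,rubrum,45.0,-93.0,2015-04-08,leaves,yes,,",
    "S3,p1,Acer,rubrum,45.0,-93.0,2015-03-01,leaves,no,,",
    "S4,p1,Acer,rubrum,45.0,-93.0,2015-03-08,leaves,unknown,,",
    "S5,p1,Acer,rubrum,45.0,-93.0,2015-03-15,mystery_code,yes,,"
  ))
  parsed <- read_status_csv(sf)
  mapped <- map_records(parsed$records, "status", mapping, catalog)

  obs <- mapped$observations
  expect_equal(obs$lower[obs$source_record_id == "S1"], 10)
  expect_equal(obs$upper[obs$source_record_id == "S1"], 20)
  expect_equal(obs$lower[obs$source_record_id == "S2"], 1)
  expect_true(is.infinite(obs$upper[obs$source_record_id == "S2"]))
  expect_equal(obs$lower[obs$source_record_id == "S3"], 0)
  expect_equal(obs$upper[obs$source_record_id == "S3"], 0)
  expect_equal(mapped$skips$reason[mapped$skips$record_id == "S4"],
               "unknown_status")
  expect_equal(mapped$skips$reason[mapped$skips$record_id == "S5"], "unmapped")

  # the intensity range materializes like the canonical 10-20 count example
  mat <- materialize(obs[obs$source_record_id == "S1", ], catalog)
  expect_setequal(mat$assertions$class_id,
                  c("true_leaf_present"))
})

test_that("event semantics date the observation and skip agricultural codes", {
  catalog <- default_catalog()
  mapping <- default_mapping(catalog)
  ef <- write_lines_tmp(c(
    event_header,
    "E1,st1,Quercus,robur,48.2,16.4,2015,BBCH11,110",
    "E2,st1,Quercus,robur,48.2,16.4,2015,BBCH99,250",
    "E3,st1,Quercus,robur,48.2,16.4,2015,BBCH42,120"
  ))
  parsed <- read_event_csv(ef)
  mapped <- map_records(parsed$records, "event", mapping, catalog)
  obs <- mapped$observations
  expect_equal(nrow(obs), 1)
  expect_equal(obs$date, as.Date("2015-04-20"))  # DOY 110 of 2015
  expect_equal(obs$lower, 1)
  expect_true(is.infinite(obs$upper))
  expect_setequal(mapped$skips$reason, c("agricultural", "unmapped"))
})

test_that("pipeline accounts for every input row and reports source shares", {
  catalog <- default_catalog()
  mapping <- default_mapping(catalog)
  sf <- write_lines_tmp(c(status_header, vapply(1:10, function(i) {
    sprintf("S%02d,p%d,Acer,,45.0,-93.0,2015-04-%02d,leaves,yes,%d,%d",
            i, i, i, i, i + 10)
  }, character(1))))
  ef <- write_lines_tmp(c(event_header, vapply(1:10, function(i) {
    code <- if (i <= 2) "BBCH99" else "BBCH11"
    sprintf("E%02d,st%d,Acer,,%.1f,%.1f,2015,%s,%d", i, i, 40 + i, 10 + i,
            code, 100 + i)
  }, character(1))))
  out <- tempfile(fileext = ".csv")
  report <- run_pipeline(list(list(dialect = "status", path = sf),
                              list(dialect = "event", path = ef)),
                         mapping, catalog, out)
  expect_equal(report$totals$rows_read, 20)
  expect_equal(report$totals$harmonized, 18)
  expect_equal(report$totals$skipped, 2)
  expect_equal(report$sources[[2]]$skip_reasons$agricultural, 2)
  expect_equal(report$totals$rows_read,
               report$totals$harmonized + report$totals$rejected +
                 report$totals$skipped)
  rows <- read_harmonized_csv(out)
  expect_equal(nrow(rows), 18)
  expect_equal(report$sources[[1]]$share_of_output, 10 / 18)
})

test_that("pipeline conservation holds on simulator output with a ledger", {
  params <- simulation_params(seed = 99, n_plants = 12, years = 2000:2003,
                              fraction_agricultural = 0.1)
  dir <- tempfile()
  sim <- simulate_dataset(params, out_dir = dir)
  out <- tempfile(fileext = ".csv")
  report <- run_pipeline(list(list(dialect = "status", path = sim$paths$status),
                              list(dialect = "event", path = sim$paths$events)),
                         default_mapping(), default_catalog(), out)
  expect_equal(report$totals$rows_read, nrow(sim$status) + nrow(sim$events))
  expect_equal(report$totals$rows_read,
               report$totals$harmonized + report$totals$rejected +
                 report$totals$skipped)
  expect_equal(report$totals$harmonized, sum(sim$ledger$n_harmonized_expected))
  expect_equal(report$sources[[2]]$skip_reasons$agricultural,
               sum(sim$ledger$event_agricultural))
})

test_that("status and event encodings of one onset infer the same classes", {
  catalog <- default_catalog()
  mapping <- default_mapping(catalog)
  # same plant, same onset day (DOY 110 of 2015 = April 20)
  sf <- write_lines_tmp(c(
    status_header,
    "S1,p1,Acer,,45.0,-93.0,2015-04-20,leaves,yes,1,10"
  ))
  ef <- write_lines_tmp(c(
    event_header,
    "E1,p1,Acer,,45.0,-93.0,2015,BBCH11,110"
  ))
  o_status <- map_records(read_status_csv(sf)$records, "status", mapping,
                          catalog)$observations
  o_event <- map_records(read_event_csv(ef)$records, "event", mapping,
                         catalog)$observations
  expect_equal(o_status$date, o_event$date)
  m_status <- materialize(o_status, catalog)$assertions$class_id
  m_event <- materialize(o_event, catalog)$assertions$class_id
  expect_setequal(m_status, m_event)
})

test_that("identical inputs produce byte-identical harmonized output", {
  params <- simulation_params(seed = 5, n_plants = 5, years = 2000:2001)
  dir <- tempfile()
  sim <- simulate_dataset(params, out_dir = dir)
  sources <- list(list(dialect = "status", path = sim$paths$status),
                  list(dialect = "event", path = sim$paths$events))
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  run_pipeline(sources, default_mapping(), default_catalog(), p1)
  run_pipeline(sources, default_mapping(), default_catalog(), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("conflicting observations are excluded and reported", {
  catalog <- default_catalog()
  mapping <- default_mapping(catalog)
  # two rows with the same record_id would merge into one contradictory
  # observation; the reader rejects the duplicate instead
  sf <- write_lines_tmp(c(
    status_header,
    "S1,p1,Acer,,45.0,-93.0,2015-04-20,leaves,yes,1,10",
    "S1,p1,Acer,,45.0,-93.0,2015-04-20,leaves,no,,"
  ))
  parsed <- read_status_csv(sf)
  expect_equal(parsed$rejects$reason, "duplicate record_id")
})
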