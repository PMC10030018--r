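# Example run configuration for the audit CLI (`ctdash audit --config ...`).
# Every key is optional; omitted keys fall back to the package defaults.

cohort:
  completion_from: 2009
  completion_to: 2017
  complete_statuses: [Completed, Terminated, Suspended, Unknown status]
  require_interventional: true
  require_start_date: false

followup:
  registry_download_date: "2022-11-01"
  publication_search_date: "2022-02-15"

# DRKS reference-title keywords flagging a registry results report
# (case-insensitive substrings)
# drks_keywords: [ergebnisbericht, abschlussbericht]

# Column-name overrides per registry dialect, merged over the defaults in
# registry_dialects()
# dialects:
#   ctgov:
#     trn: nct_number
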