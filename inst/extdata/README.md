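# Synthetic reference datasets

All tables in this directory are **synthetic**: noise-free curves produced
by the package's own dynamic population-pharmacokinetic model (see
`data-raw/fixtures.R` for the generating script and
`fixtures_meta.csv` for the exact parameter values). They represent four
archetypal POP monitoring situations in ~30-year-old mothers:

| chemical | situation |
|----------|-----------|
| BDE47    | rapidly eliminated (2.2 y), recent phaseout (1995), intake halving 6.8 y |
| DDT      | rapidly eliminated (2 y), old ban (1970) |
| PCB153   | slowly eliminated (15 y) — the classic failure case of the static inverse tool |
| HCB      | intermediate elimination (6 y) with a slowly declining intake (12 y) |

Parameter values are literature-typical for the named chemicals; the
tables are stand-ins for empirical monitoring data and must not be used
as measurements. File naming: `cstd_<chem>_synthetic.csv`
(year, age, conc_ng_per_g_lipid, n) and `intake_<chem>_synthetic.csv`
(year, intake_ng_per_kg_bw_per_day).
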