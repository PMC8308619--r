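file,column,type,description
counties.csv,county_id,integer,Unique county identifier (odd-number scheme; 2i-1 for the i-th county alphabetically)
counties.csv,name,text,County name
counties.csv,region,enum west|east,Side of the Cascade crest
counties.csv,area_ha,numeric > 0,County land area in hectares
counties.csv,timber_excluded,boolean,TRUE where more than 50% of forestland is at high or extreme wildfire risk (county excluded from the timber pathway)
baselines.csv,county_id,integer,County the record belongs to
baselines.csv,pathway,enum,Reporting pathway label from the closed activity registry
baselines.csv,sub_activity,text,Sub-activity label ('' when the pathway has none)
baselines.csv,ownership,enum private|state|federal|other|na,Land ownership split (timber and replanting) or 'na'
baselines.csv,year,integer or empty,Calendar year for annual-series records; empty for single-rate records
baselines.csv,amount,numeric >= 0,Annual activity amount in the row's units
baselines.csv,units,enum ha_per_yr|volume_per_yr|kgN_per_yr,Activity unit label; must match the resolved rate's units
baselines.csv,max_resource,numeric >= 0 or empty,Total implementable resource stock in activity units (empty = unlimited)
rates.csv,pathway,enum,Activity key component
rates.csv,sub_activity,text,Activity key component
rates.csv,ownership,enum,Activity key component
rates.csv,region,enum west|east|statewide,Region the rate applies to; statewide rows are the fallback
rates.csv,mean_rate,numeric signed,MT CO2e per activity unit per year; negative = net removal or avoided emission
rates.csv,sd_rate,numeric >= 0,Standard deviation of the rate (Monte Carlo uncertainty)
rates.csv,units,enum,Activity unit the rate is expressed per
rates.csv,age_profile,text or empty,profile_id of the age profile for cohort activities
scenario_params.csv,scenario,enum limited|moderate|ambitious,Scenario the row parameterises
scenario_params.csv,pathway,enum,Activity key component
scenario_params.csv,sub_activity,text,Activity key component
scenario_params.csv,ownership,enum,Activity key component
scenario_params.csv,ramp_fraction,numeric (0-1],Per-year ramp increment as a fraction of allowed growth during years 1-10
scenario_params.csv,growth_share,numeric [0-1],Fraction of historical variation allowed as growth
scenario_params.csv,post_decade_share,numeric [0-1],Multiplier on the year-10 increment applied in years 11-31 (1 = hold)
scenario_params.csv,cap_fraction,numeric [0-1],Maximum fraction of max_resource that may be enrolled
scenario_params.csv,flux_mode,enum stock|pulse,Whether flux accrues on cumulative enrollment or on the year's new enrollment only
age_profiles.csv,profile_id,text,Profile identifier referenced from rates.csv
age_profiles.csv,age,integer,Stand/cohort age in years; must start at 1 and increase strictly
age_profiles.csv,multiplier,numeric,Step-function rate multiplier relative to the activity's mean rate
results_long.csv,geography,text,County id or 'statewide'
results_long.csv,pathway,text,Pathway label or 'total'
results_long.csv,sub_activity,text,Sub-activity label or ''
results_long.csv,scenario,enum,Scenario label
results_long.csv,year,integer 1-31,Simulation year (1 = 2020 ... 31 = 2050)
results_long.csv,median,numeric signed,Median annual flux over iterations; MMT CO2e per yr
results_long.csv,p05,numeric signed,5th percentile of the signed annual flux over iterations (most negative bound for reductions)
results_long.csv,p95,numeric signed,95th percentile of the signed annual flux over iterations
results_long.csv,cumulative_median,numeric signed,Median over iterations of the cumulative flux; MMT CO2e
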