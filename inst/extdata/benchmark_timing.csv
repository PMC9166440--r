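metric,statistic,manual,semi_automated
minutes_per_patient,median,21.5,6.9
minutes_per_patient,iqr,16.0,9.5
seconds_per_report,median,60.0,30.0
seconds_per_report,iqr,90.0,80.0
reports_per_patient,mean,12.75,9.96
reports_per_patient,sd,10.50,9.41
total_reports,count,204,239
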