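level,position,metric,value,n_total,n_studies,imputed
youth,overall,hits_per_season,206.4,,,FALSE
high_school,overall,hits_per_season,538.7,,,FALSE
college,overall,hits_per_season,526.0,,,FALSE
youth,DL,hits_per_season,,,,
high_school,DL,hits_per_season,782.3,,,FALSE
college,DL,hits_per_season,840.9,,,FALSE
youth,DB,hits_per_season,,,,
high_school,DB,hits_per_season,316.6,,,FALSE
college,DB,hits_per_season,371.6,,,FALSE
youth,LB,hits_per_season,,,,
high_school,LB,hits_per_season,460.2,,,FALSE
college,LB,hits_per_season,539.0,,,FALSE
youth,OL,hits_per_season,,,,
high_school,OL,hits_per_season,734.4,,,FALSE
college,OL,hits_per_season,814.6,,,FALSE
youth,QB,hits_per_season,,,,
high_school,QB,hits_per_season,320.2,,,FALSE
college,QB,hits_per_season,209.4,,,FALSE
youth,RB,hits_per_season,,,,
high_school,RB,hits_per_season,475.1,,,FALSE
college,RB,hits_per_season,421.7,,,FALSE
youth,TE,hits_per_season,,,,
high_school,TE,hits_per_season,517.4,,,FALSE
college,TE,hits_per_season,599.2,,,FALSE
youth,WR,hits_per_season,,,,
high_school,WR,hits_per_season,301.9,,,FALSE
college,WR,hits_per_season,313.9,,,FALSE
youth,overall,linear_accel,20.6,,,FALSE
high_school,overall,linear_accel,26.5,,,FALSE
college,overall,linear_accel,20.6,,,FALSE
youth,DL,linear_accel,,,,
high_school,DL,linear_accel,25.8,,,FALSE
college,DL,linear_accel,21.0,,,FALSE
youth,DB,linear_accel,,,,
high_school,DB,linear_accel,28.5,,,FALSE
college,DB,linear_accel,20.2,,,FALSE
youth,LB,linear_accel,,,,
high_school,LB,linear_accel,27.3,,,FALSE
college,LB,linear_accel,22.3,,,FALSE
youth,OL,linear_accel,,,,
high_school,OL,linear_accel,25.8,,,FALSE
college,OL,linear_accel,21.0,,,FALSE
youth,QB,linear_accel,,,,
high_school,QB,linear_accel,26.8,,,FALSE
college,QB,linear_accel,21.0,,,FALSE
youth,RB,linear_accel,,,,
high_school,RB,linear_accel,27.7,,,FALSE
college,RB,linear_accel,21.8,,,FALSE
youth,TE,linear_accel,,,,
high_school,TE,linear_accel,27.1,,,FALSE
college,TE,linear_accel,31.0,,,FALSE
youth,WR,linear_accel,,,,
high_school,WR,linear_accel,28.8,,,FALSE
college,WR,linear_accel,19.5,,,FALSE
youth,overall,rotational_accel,1203.4,,,FALSE
high_school,overall,rotational_accel,1898.4,,,FALSE
college,overall,rotational_accel,1574.2,,,FALSE
youth,DL,rotational_accel,,,,
high_school,DL,rotational_accel,1801.3,,,FALSE
college,DL,rotational_accel,1806,,,FALSE
youth,DB,rotational_accel,,,,
high_school,DB,rotational_accel,1957.4,,,FALSE
college,DB,rotational_accel,,,,
youth,LB,rotational_accel,,,,
high_school,LB,rotational_accel,1870.4,,,FALSE
college,LB,rotational_accel,2071.7,,,FALSE
youth,OL,rotational_accel,,,,
high_school,OL,rotational_accel,1777.5,,,FALSE
college,OL,rotational_accel,1782,,,FALSE
youth,QB,rotational_accel,,,,
high_school,QB,rotational_accel,1476.4,,,FALSE
college,QB,rotational_accel,,,,
youth,RB,rotational_accel,,,,
high_school,RB,rotational_accel,1807.7,,,FALSE
college,RB,rotational_accel,1878.8,,,FALSE
youth,TE,rotational_accel,,,,
high_school,TE,rotational_accel,1625.8,,,FALSE
college,TE,rotational_accel,1815.7,,,FALSE
youth,WR,rotational_accel,,,,
high_school,WR,rotational_accel,2223.8,,,FALSE
college,WR,rotational_accel,,,,
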