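metric,year,term,ss,df
degree,2017,dist_nearest_point,280.00,1
degree,2017,n_adjacent,9019.00,1
degree,2017,stage,14190.00,2
degree,2017,sex,15.00,1
degree,2017,stage:sex,868.00,2
degree,2017,residuals,37534.00,159
degree,2018,dist_nearest_point,643.00,1
degree,2018,n_adjacent,11695.50,1
degree,2018,stage,13759.90,2
degree,2018,sex,166.40,1
degree,2018,stage:sex,203.50,2
degree,2018,residuals,29890.20,164
betweenness,2017,dist_nearest_point,0.0000,1
betweenness,2017,n_adjacent,0.0016,1
betweenness,2017,stage,0.0100,2
betweenness,2017,sex,0.0004,1
betweenness,2017,stage:sex,0.0028,2
betweenness,2017,residuals,0.1207,159
betweenness,2018,dist_nearest_point,0.0002,1
betweenness,2018,n_adjacent,0.0002,1
betweenness,2018,stage,0.0110,2
betweenness,2018,sex,0.0002,1
betweenness,2018,stage:sex,0.0001,2
betweenness,2018,residuals,0.0714,164
clustering,2017,dist_nearest_point,0.000,1
clustering,2017,n_adjacent,0.541,1
clustering,2017,stage,1.507,2
clustering,2017,sex,0.004,1
clustering,2017,stage:sex,0.021,2
clustering,2017,residuals,3.137,155
clustering,2018,dist_nearest_point,0.026,1
clustering,2018,n_adjacent,0.207,1
clustering,2018,stage,0.485,2
clustering,2018,sex,0.003,1
clustering,2018,stage:sex,0.007,2
clustering,2018,residuals,2.880,164
unique_points,2017,dist_nearest_point,23.29,1
unique_points,2017,n_adjacent,174.86,1
unique_points,2017,stage,362.22,2
unique_points,2017,sex,1.41,1
unique_points,2017,stage:sex,18.61,2
unique_points,2017,residuals,760.94,153
unique_points,2018,dist_nearest_point,8.31,1
unique_points,2018,n_adjacent,194.03,1
unique_points,2018,stage,373.13,2
unique_points,2018,sex,8.46,1
unique_points,2018,stage:sex,13.37,2
unique_points,2018,residuals,778.13,164
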