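mun_mgdl,bw_kg,dmi_kg,cp_pct,diet,study_id,un_gd,un_sem,n_intake_gd
11.946,618.916,19.233,15.23,TMR,10.1000/synth.tmr.001,176.976,11.234,468.677
12.907,603.825,19.536,14.559,TMR,10.1000/synth.tmr.001,168.725,11.497,455.063
12.488,567.742,17.723,15.105,TMR,10.1000/synth.tmr.001,169.617,10.097,428.335
9.113,601.605,23.792,14.752,TMR,10.1000/synth.tmr.002,126.303,11.974,561.571
8.406,674.603,26.154,13.481,TMR,10.1000/synth.tmr.002,132.895,12.165,564.144
8.882,753.906,23.741,15.512,TMR,10.1000/synth.tmr.003,176.499,7.161,589.236
9.414,741.362,22.105,15.259,TMR,10.1000/synth.tmr.003,167.08,10.402,539.691
5.557,702.086,24.185,14.866,TMR,10.1000/synth.tmr.003,137.214,13.479,575.249
13.161,633.114,23.833,16.287,TMR,10.1000/synth.tmr.004,153.061,9.472,621.071
8.985,639.265,23.531,15.479,TMR,10.1000/synth.tmr.004,111.95,11.051,582.788
14.98,686.953,25.13,16.452,TMR,10.1000/synth.tmr.004,167.266,14.801,661.516
12.395,673.765,20.68,15.359,TMR,10.1000/synth.tmr.005,143.349,9.061,508.201
10.906,767.946,24.308,15.412,TMR,10.1000/synth.tmr.005,154.544,8.074,599.408
14.395,433.655,16.604,19.062,PASTURE,10.1000/synth.pasture.001,158.602,12.563,506.388
16.028,422.346,13.498,19.099,PASTURE,10.1000/synth.pasture.001,165.106,9.003,412.469
15.74,658.713,16.597,22.317,PASTURE,10.1000/synth.pasture.002,318.607,4.85,592.622
17.803,633.592,14.771,19.625,PASTURE,10.1000/synth.pasture.002,283.436,13.015,463.817
18.695,642.369,15.218,23.688,PASTURE,10.1000/synth.pasture.002,368.359,11.759,576.783
16.598,401.637,14.498,19.514,PASTURE,10.1000/synth.pasture.003,134.444,10.286,452.672
14.867,433.681,13.794,14.381,PASTURE,10.1000/synth.pasture.003,78.969,13.599,317.386
17.021,381.431,16.834,18.065,PASTURE,10.1000/synth.pasture.003,120.259,9.412,486.557
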