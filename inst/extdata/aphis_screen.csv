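compound_id,goldscore_ache,goldscore_nachr,goldscore_cht,moldock_ache,moldock_nachr,moldock_cht,prob_comb_ache,prob_comb_nachr,prob_comb_cht,le_ache,le_nachr,le_cht,p_activity,is_reference
1800,51.28,34.20,94.04,-174.03,-148.66,-224.29,0.70,0.74,0.70,-2.63,-2.25,-3.39,0.61,0
1804,40.87,31.15,113.8,-120.62,-135.97,-219.43,0.64,0.74,0.75,-1.94,-2.19,-3.53,0.66,0
1809,35.86,21.23,170.0,-223.77,-138.22,-176.35,0.75,0.70,0.73,-4.30,-2.65,-3.39,0.61,0
1836,42.24,23.48,127.8,-217.92,-162.71,-240.23,0.76,0.76,0.76,-3.11,-2.32,-3.43,0.62,0
1840,42.40,25.73,142.0,-108.98,-111.3,-219.83,0.63,0.68,0.78,-1.72,-1.76,-3.48,0.66,0
1842,60.92,32.90,45.7,-162.09,-140.75,-181.34,0.73,0.76,0.64,-2.57,-2.23,-2.87,0.66,0
1845,44.70,32.30,120.2,-149.98,-129.73,-179.35,0.68,0.73,0.71,-2.34,-2.02,-2.80,0.65,0
1854,41.30,32.00,71.5,-162.01,-139.78,-194.60,0.64,0.70,0.62,-3.24,-2.79,-3.89,0.57,0
1855,35.71,27.91,76.3,-148.07,-107.61,-170.44,0.62,0.63,0.61,-2.84,-2.06,-3.27,0.58,0
1910,33.08,33.24,77.8,-126.98,-148.83,-198.84,0.59,0.72,0.64,-2.39,-2.80,-3.75,0.58,0
1931,45.20,36.38,99.8,-180.50,-140.90,-197.69,0.73,0.76,0.71,-2.86,-2.23,-3.13,0.66,0
1932,45.07,29.28,92.2,-149.64,-141.42,-183.22,0.68,0.74,0.68,-2.37,-2.24,-2.90,0.64,0
1933,32.84,30.35,79.4,-142.05,-147.59,-191.20,0.64,0.75,0.66,-2.15,-2.23,-2.89,0.63,0
1934,41.82,30.02,125.7,-154.26,-89.66,-195.89,0.70,0.65,0.74,-2.41,-1.40,-3.06,0.67,0
1936,28.17,32.95,63.9,-172.98,-139.01,-206.48,0.70,0.76,0.69,-2.36,-1.90,-2.82,0.67,0
insecticide,29.34,39.26,62.0,-88.38,-55.89,-146.23,,,,-5.19,-3.7,-3.4,,1
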