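compound_id,goldscore_ache,goldscore_nachr,goldscore_cht,moldock_ache,moldock_nachr,moldock_cht,prob_comb_ache,prob_comb_nachr,prob_comb_cht,le_ache,le_nachr,le_cht,p_activity,is_reference
21,35.26,31.61,33.90,-122.70,-66.47,-88.32,0.67,0.65,,-4.90,-2.65,-3.53,0.58,0
44,33.55,27.08,32.12,-117.86,-80.01,-106.16,0.66,0.67,,-4.71,-3.20,-4.24,0.58,0
46,32.36,25.65,31.48,-127.86,-77.01,-90.17,0.67,0.66,,-5.11,-3.08,-3.60,0.57,0
47,32.63,28.45,42.33,-125.16,-83.84,-107.76,0.67,0.68,,-5.00,-3.35,-4.31,0.57,0
51,36.68,33.86,42.50,-138.59,-87.14,-92.41,0.70,0.71,,-5.54,-3.48,-3.69,0.57,0
67,38.28,24.51,33.76,-124.82,-91.09,-99.81,0.67,0.69,,-4.99,-3.64,-3.99,0.56,0
77,22.53,26.14,38.41,-133.84,-84.06,-109.86,0.69,0.71,,-5.35,-3.36,-4.39,0.62,0
95,30.27,23.47,33.67,-138.23,-79.21,-116.49,0.69,0.66,,-5.52,-3.16,-4.65,0.58,0
111,35.09,28.31,31.66,-125.26,-82.99,-100.81,0.66,0.67,,-5.01,-3.31,-4.03,0.56,0
131,33.19,24.81,29.23,-91.223,-71.29,-99.12,0.57,0.60,,-3.64,-2.85,-3.96,0.52,0
151,23.97,25.21,31.02,-142.60,-87.13,-93.69,0.71,0.71,,-5.48,-3.35,-3.60,0.61,0
163,23.82,26.01,32.97,-157.95,-78.03,-114.73,0.72,0.67,,-6.07,-3.00,-4.41,0.58,0
164,25.68,29.30,29.76,-157.91,-78.19,-114.72,0.72,0.68,,-6.07,-3.00,-4.41,0.58,0
199,15.86,25.26,35.87,-139.51,-97.99,-123.03,0.63,0.68,,-4.98,-3.49,-4.39,0.52,0
200,37.46,31.27,29.79,-139.30,-88.29,-100.49,0.67,0.67,,-4.97,-3.15,-3.58,0.52,0
231,35.87,24.74,41.80,-145.84,-85.64,-101.52,0.64,0.61,,-5.60,-3.29,-3.90,0.46,0
245,14.49,24.76,29.38,-137.39,-99.41,-136.65,0.54,0.60,,-4.43,-3.20,-4.40,0.39,0
273,43.55,27.57,31.78,-143.21,-90.84,-127.36,0.67,0.65,,-5.30,-3.36,-4.71,0.49,0
342,34.26,27.46,36.14,-141.28,-72.29,-107.30,0.73,0.67,,-5.65,-2.89,-4.29,0.61,0
434,38.55,29.14,31.53,-138.24,-69.37,-103.72,0.66,0.61,,-5.31,-2.66,-3.98,0.51,0
437,34.95,26.10,32.63,-143.25,-73.66,-121.15,0.73,0.67,,-5.73,-2.94,-4.84,0.61,0
438,31.35,25.49,36.05,-143.33,-74.69,-121.91,0.72,0.67,,-5.73,-2.98,-4.87,0.61,0
442,21.30,29.32,43.77,-147.15,-95.97,-138.47,0.71,0.74,,-5.88,-3.83,-5.53,0.6,0
450,30.09,25.94,45.40,-123.18,-97.99,-112.14,0.68,0.74,,-4.92,-3.91,-4.48,0.6,0
483,30.03,22.82,44.95,-112.04,-85.51,-86.760,0.62,0.65,,-4.48,-3.42,-3.47,0.54,0
709,34.00,26.91,27.69,-143.94,-88.47,,0.67,0.66,,-4.96,-3.05,-4.07,0.52,0
759,28.98,31.15,31.87,-119.82,-80.56,-104.55,0.62,0.66,,-4.60,-3.09,-4.02,0.53,0
787,27.42,24.15,43.73,-120.17,-77.32,-103.20,0.66,0.67,,-4.62,-2.97,-3.96,0.6,0
1015,16.47,22.09,29.89,-122.68,-93.87,-132.03,0.57,0.64,,-4.23,-3.23,-4.55,0.48,0
1027,27.07,24.94,40.30,-124.98,-69.30,-80.09,0.63,0.61,,-4.80,-2.66,-3.08,0.53,0
1086,26.71,22.69,43.52,-170.37,-103.44,-141.82,0.68,0.66,,-6.08,-3.69,-5.06,0.47,0
1184,24.34,27.89,40.64,-153.42,-97.36,-125.27,0.65,0.67,,-5.11,-3.24,-4.17,0.49,0
1195,29.74,25.35,43.36,-157.71,-84.13,-124.31,0.75,0.70,,-6.30,-3.36,-4.97,0.61,0
1302,33.25,22.08,29.37,-143.96,-62.90,-93.11,0.65,0.55,,-4.79,-2.09,-3.10,0.49,0
1350,33.07,28.87,30.85,-121.54,-87.82,-98.21,0.63,0.67,,-4.67,-3.37,-3.77,0.53,0
1823,3.18,21.94,31.33,-135.14,-93.79,-110.04,0.56,0.63,,-4.50,-3.12,-3.66,0.47,0
1892,20.84,17.26,29.68,-132.10,-80.46,-108.72,0.62,0.60,,-4.89,-2.98,-4.02,0.51,0
insecticide,32.12,22.58,37.19,-59.87,-55.07,-163.72,,,,-5.9,-3.6,-3.8,,1
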