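[{"x": [1.0, 3.0, 7.0, 2.0, 4.0, 5.0, 7.0, 7.0, 0.0, 4.0, 0.0, 2.0, 0.0, 4.0, 4.0, 0.0, 3.0, 7.0, 7.0, 7.0, 6.0, 7.0, 6.0, 7.0, 3.0, 1.0, 5.0, 1.0, 2.0, 2.0, 2.0, 5.0, 7.0, 3.0, 6.0, 5.0, 4.0, 3.0], "y": [-1, -1, -1, 1, 1, 1, -1, -1, 1, -1, 1, -1, 1, 1, 1, 1, -1, -1, -1, -1, 1, -1, 1, 1, 1, -1, -1, -1, 1, 1, 1, 1, -1, -1, 1, -1, -1, -1], "C": 10.0, "w": -0.2857142857142776, "b": 1.0, "obj": 305.755102040819}, {"x": [6.0, 0.0, 2.0, 4.0, 4.0, 3.0, 4.0, 1.0, 4.0, 2.0, 0.0, 4.0, 5.0, 5.0, 4.0, 6.0, 4.0, 5.0, 2.0, 6.0, 2.0, 7.0, 0.0, 6.0, 7.0, 0.0, 5.0, 4.0, 6.0, 6.0, 6.0, 2.0, 4.0, 4.0, 7.0, 7.0, 1.0, 7.0], "y": [-1, 1, -1, -1, -1, 1, 1, -1, 1, -1, -1, 1, -1, 1, -1, 1, -1, -1, -1, -1, 1, -1, -1, 1, -1, 1, -1, -1, 1, 1, 1, 1, -1, 1, 1, -1, -1, -1], "C": 0.1, "w": -1.3877787807814457e-16, "b": -1.0, "obj": 3.200000000000001}, {"x": [2.0, 5.0, 6.0, 3.0, 2.0, 5.0, 7.0, 4.0, 7.0, 7.0, 6.0, 7.0, 3.0, 1.0, 5.0, 7.0, 0.0, 5.0, 4.0, 1.0], "y": [1, -1, 1, -1, -1, -1, -1, -1, 1, -1, 1, 1, 1, -1, 1, 1, -1, 1, 1, 1], "C": 0.1, "w": 0.2857142857142855, "b": -0.9999999999999999, "obj": 1.6979591836734698}, {"x": [4.0, 3.0, 5.0, 3.0, 0.0, 1.0, 3.0, 3.0, 0.0, 2.0, 0.0, 1.0, 3.0, 2.0, 3.0, 3.0, 6.0, 6.0, 5.0, 6.0], "y": [1, -1, 1, -1, -1, 1, 1, -1, 1, -1, -1, -1, 1, 1, 1, 1, -1, -1, -1, -1], "C": 0.1, "w": -2.7755575615628914e-17, "b": -1.0, "obj": 1.8}, {"x": [3.0, 4.0, 0.0, 0.0, 7.0, 1.0, 7.0, 2.0, 0.0, 4.0, 6.0, 7.0, 6.0, 0.0, 0.0, 1.0, 0.0, 6.0, 7.0, 6.0], "y": [-1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, 1, -1, -1, -1, -1, 1, 1, -1], "C": 1.0, "w": 0.0, "b": -0.9999999999999982, "obj": 6.000000000000025}, {"x": [7.0, 0.0, 2.0, 4.0, 7.0, 6.0, 1.0, 7.0, 7.0, 2.0, 6.0, 1.0, 2.0, 4.0, 5.0, 1.0, 1.0, 0.0, 5.0, 7.0, 4.0, 0.0, 0.0, 1.0, 7.0, 2.0, 4.0, 4.0, 3.0, 5.0, 0.0, 3.0, 7.0, 6.0, 5.0, 4.0, 6.0, 7.0], "y": [-1, -1, -1, 1, 1, 1, -1, -1, 1, -1, 1, -1, -1, -1, 1, 1, -1, -1, -1, 1, 1, 1, 1, 1, 1, 1, -1, 1, -1, -1, 1, 1, 1, -1, -1, -1, 1, -1], "C": 1.0, "w": 0.2857142857142847, "b": -0.9999999999999997, "obj": 34.89795918367348}, {"x": [3.0, 5.0, 5.0, 0.0, 6.0, 6.0, 5.0, 0.0, 1.0, 4.0, 6.0, 6.0, 6.0, 1.0, 1.0, 1.0, 7.0, 0.0, 2.0, 0.0], "y": [-1, 1, 1, 1, -1, 1, -1, 1, -1, -1, 1, -1, -1, 1, -1, -1, 1, -1, -1, -1], "C": 1.0, "w": 0.0, "b": -1.0, "obj": 16.0}, {"x": [6.0, 2.0, 3.0, 2.0], "y": [-1, -1, 1, 1], "C": 10.0, "w": -0.4999999999999982, "b": 2.0000000000000027, "obj": 25.125000000000114}, {"x": [1.0, 0.0, 2.0, 5.0], "y": [1, -1, 1, -1], "C": 1.0, "w": -0.5000000000000004, "b": 1.5000000000000009, "obj": 3.125000000000001}, {"x": [5.0, 5.0, 5.0, 5.0, 4.0, 1.0, 3.0, 4.0, 2.0, 2.0, 7.0, 2.0, 3.0, 6.0, 0.0, 7.0, 6.0, 2.0, 1.0, 6.0], "y": [-1, -1, 1, -1, 1, -1, 1, 1, 1, 1, 1, -1, 1, -1, 1, -1, -1, 1, -1, -1], "C": 10.0, "w": -0.4999999999999929, "b": 1.9999999999999942, "obj": 155.12500000000063}, {"x": [3.0, 0.0, 2.0, 6.0], "y": [-1, 1, 1, -1], "C": 0.1, "w": -0.3333333333333334, "b": 0.9999999999999999, "obj": 0.22222222222222227}, {"x": [3.0, 6.0, 3.0, 3.0, 2.0, 7.0, 0.0, 2.0], "y": [1, 1, 1, -1, -1, -1, -1, 1], "C": 10.0, "w": 0.3333333333333357, "b": -0.9999999999999947, "obj": 73.38888888888904}]
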