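{"schema":1,"type":"tg_surrogate","units":"s","order":8,"coefficients":[{"i":0,"j":0,"value":-0.00012727655582975441},{"i":1,"j":0,"value":0.30283142663010398},{"i":0,"j":1,"value":-0.061431430424771186},{"i":2,"j":0,"value":11.66843454516567},{"i":1,"j":1,"value":-14.656049934902619},{"i":0,"j":2,"value":2.7776831971235145},{"i":3,"j":0,"value":85.49469979966625},{"i":2,"j":1,"value":-316.93308206850458},{"i":1,"j":2,"value":274.89920861359826},{"i":0,"j":3,"value":-45.273837046987452},{"i":4,"j":0,"value":543.71909708773171},{"i":3,"j":1,"value":-2364.3148841071352},{"i":2,"j":2,"value":4038.3129053115808},{"i":1,"j":3,"value":-2554.8365737475292},{"i":0,"j":4,"value":364.28396484250339},{"i":5,"j":0,"value":1586.8553655602418},{"i":4,"j":1,"value":-9967.9512506601877},{"i":3,"j":2,"value":22996.246413621106},{"i":2,"j":3,"value":-25985.195022828178},{"i":1,"j":4,"value":12842.935517494918},{"i":0,"j":5,"value":-1603.6720233154804},{"i":6,"j":0,"value":3422.0023011158846},{"i":5,"j":1,"value":-22896.631987283705},{"i":4,"j":2,"value":67435.85714254083},{"i":3,"j":3,"value":-103888.79795258175},{"i":2,"j":4,"value":87813.708788815871},{"i":1,"j":5,"value":-35503.658744160377},{"i":0,"j":6,"value":3931.5273996815881},{"i":7,"j":0,"value":2971.247863522618},{"i":6,"j":1,"value":-27035.382753994454},{"i":5,"j":2,"value":96705.434670684393},{"i":4,"j":3,"value":-189973.47397444374},{"i":3,"j":4,"value":219724.75519074412},{"i":2,"j":5,"value":-148434.7261971338},{"i":1,"j":6,"value":50694.656464415544},{"i":0,"j":7,"value":-5034.6950488047269},{"i":8,"j":0,"value":561.15105257454229},{"i":7,"j":1,"value":-8663.0833235642931},{"i":6,"j":2,"value":45879.945267706571},{"i":5,"j":3,"value":-120463.15532591564},{"i":4,"j":4,"value":184934.49684129655},{"i":3,"j":5,"value":-174070.94046782708},{"i":2,"j":6,"value":98543.836674275823},{"i":1,"j":7,"value":-29157.507880972498},{"i":0,"j":8,"value":2623.3710763458207}],"training":{"grid_start":0.0025000000000000001,"grid_stop":0.505,"grid_spacing":0.0074999999999999997,"seed":42,"train_fraction":0.84999999999999998,"n_points":2810,"n_train":2388,"rmse":0.0004879774942517455,"r_squared":0.99982491841587184},"envelope":{"min":0.0025000000000000001,"max":0.50499999999999989},"package_version":"0.1.0"}
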