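"individual_id","date","occasion","item_text","calories"
"1","2014-09-01","breakfast","Latte, 12 oz",150
"1","2014-09-01","breakfast","Muffin, 1",350
"1","2014-09-01","lunch","Chicken salad, 1 bowl",450
"1","2014-09-01","dinner","Pasta, 1 plate",600
"1","2014-09-01","snacks","Apple, 1",95
"1","2014-09-02","breakfast","Latte, 12 oz",150
"1","2014-09-02","lunch","Chicken salad, 1 bowl",450
"1","2014-09-02","dinner","Pasta, 1 plate",600
"1","2014-09-02","snacks","Apple, 1",95
"1","2014-09-03","breakfast","Latte, 12 oz",150
"1","2014-09-03","breakfast","Muffin, 1",350
"1","2014-09-03","lunch","Chicken salad, 1 bowl",450
"1","2014-09-03","dinner","Pasta, 1 plate",600
"1","2014-09-03","snacks","Apple, 1",95
"1","2014-09-05","breakfast","Latte, 12 oz",150
"1","2014-09-05","breakfast","Croissant, 1",280
"1","2014-09-05","lunch","Chicken salad, 1 bowl",450
"1","2014-09-05","dinner","Pasta, 1 plate",600
"1","2014-09-05","snacks","Apple, 1",95
"1","2014-09-06","breakfast","Latte, 12 oz",150
"1","2014-09-06","lunch","Chicken salad, 1 bowl",450
"1","2014-09-06","dinner","Pasta, 1 plate",600
"1","2014-09-06","snacks","Apple, 1",95
"1","2014-09-08","breakfast","Latte, 12 oz",150
"1","2014-09-08","lunch","Chicken salad, 1 bowl",450
"1","2014-09-08","dinner","Pasta, 1 plate",600
"1","2014-09-08","snacks","Apple, 1",95
"1","2014-09-09","breakfast","Latte, 12 oz",150
"1","2014-09-09","breakfast","Muffin, 1",350
"1","2014-09-09","lunch","Chicken salad, 1 bowl",450
"1","2014-09-09","dinner","Pasta, 1 plate",600
"1","2014-09-09","snacks","Apple, 1",95
"1","2014-09-10","breakfast","Latte, 12 oz",150
"1","2014-09-10","breakfast","Muffin, 1",350
"1","2014-09-10","lunch","Chicken salad, 1 bowl",450
"1","2014-09-10","dinner","Pasta, 1 plate",600
"1","2014-09-10","snacks","Apple, 1",95
"1","2014-09-12","breakfast","Latte, 12 oz",150
"1","2014-09-12","lunch","Chicken salad, 1 bowl",450
"1","2014-09-12","dinner","Pasta, 1 plate",600
"1","2014-09-12","snacks","Apple, 1",95
"1","2014-09-13","breakfast","Latte, 12 oz",150
"1","2014-09-13","breakfast","Muffin, 1",350
"1","2014-09-13","lunch","Chicken salad, 1 bowl",450
"1","2014-09-13","dinner","Pasta, 1 plate",600
"1","2014-09-13","snacks","Apple, 1",95
"1","2014-09-15","breakfast","Latte, 12 oz",150
"1","2014-09-15","breakfast","Muffin, 1",350
"1","2014-09-15","lunch","Chicken salad, 1 bowl",450
"1","2014-09-15","dinner","Pasta, 1 plate",600
"1","2014-09-15","snacks","Apple, 1",95
"1","2014-09-16","breakfast","Muffin, 1",350
"1","2014-09-16","breakfast","Hot-chocolate, 8 oz",200
"1","2014-09-16","lunch","Chicken salad, 1 bowl",450
"1","2014-09-16","dinner","Pasta, 1 plate",600
"1","2014-09-16","snacks","Apple, 1",95
"1","2014-09-17","breakfast","Latte, 12 oz",150
"1","2014-09-17","lunch","Chicken salad, 1 bowl",450
"1","2014-09-17","dinner","Pasta, 1 plate",600
"1","2014-09-17","snacks","Apple, 1",95
"1","2014-09-19","breakfast","Latte, 12 oz",150
"1","2014-09-19","breakfast","Muffin, 1",350
"1","2014-09-19","lunch","Chicken salad, 1 bowl",450
"1","2014-09-19","dinner","Pasta, 1 plate",600
"1","2014-09-19","snacks","Apple, 1",95
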