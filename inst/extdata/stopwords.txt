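# common stop-word list (Fox-style subset)
a
about
above
after
again
all
almost
also
although
among
an
and
another
any
are
as
at
be
because
been
before
being
between
both
but
by
can
could
did
do
does
during
each
either
for
from
further
had
has
have
having
here
how
however
if
in
into
is
it
its
itself
just
may
might
more
most
much
must
no
nor
not
of
on
only
or
other
our
out
over
per
several
should
since
so
some
such
than
that
the
their
them
then
there
these
they
this
those
through
thus
to
under
until
up
upon
was
we
were
what
when
where
which
while
who
will
with
within
without
would
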